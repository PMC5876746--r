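test_that("RANSAC accepts clean spheres and enforces both gates", {
  pts <- sphere_points(2000, c(10, 20, 30), 5, seed = 1)
  m <- ransac_sphere(pts, detection_params(), seed = 2)
  expect_s3_class(m, "sphere_model")
  expect_equal(m$radius, 5, tolerance = 1e-6)
  expect_equal(m$center, c(10, 20, 30), tolerance = 1e-6)
  expect_gte(length(m$inliers), 1999)

  # radius below the 1 mm berry gate
  tiny <- sphere_points(2000, c(0, 0, 0), 0.5, seed = 3)
  expect_null(ransac_sphere(tiny, detection_params(), seed = 4))
  # radius above the 9 mm gate
  big <- sphere_points(2000, c(0, 0, 0), 12, seed = 5)
  expect_null(ransac_sphere(big, detection_params(), seed = 6))
  # 99 points: below the 100-supporter gate
  few <- sphere_points(99, c(0, 0, 0), 5, seed = 7)
  expect_null(ransac_sphere(few, detection_params(), seed = 8))
})

test_that("RANSAC is robust to clutter and deterministic under a seed", {
  set.seed(9)
  good <- sphere_points(1400, c(25, 25, 25), 6)
  clutter <- matrix(runif(1800, 10, 40), ncol = 3)  # 30% uniform clutter
  pts <- rbind(good, clutter)
  m1 <- ransac_sphere(pts, detection_params(), seed = 10)
  m2 <- ransac_sphere(pts, detection_params(), seed = 10)
  expect_identical(m1, m2)
  expect_equal(m1$radius, 6, tolerance = 0.1)
  # inlier set excludes nearly all clutter
  clutter_in <- sum(m1$inliers > 1400)
  expect_lt(clutter_in / 1800, 0.05)

  # every inlier satisfies the distance band invariant
  d <- abs(sqrt(rowSums(sweep(pts[m1$inliers, ], 2, m1$center, "-")^2)) -
             m1$radius)
  expect_lte(max(d), detection_params()$inlier_distance + 1e-12)
})

test_that("pure noise regions yield no sphere model", {
  set.seed(12)
  noise <- matrix(runif(1500, 0, 40), ncol = 3)
  expect_null(ransac_sphere(noise, detection_params(), seed = 13))
  expect_length(detect_berries_in_region(noise, detection_params(),
                                         seed = 14), 0)
})

test_that("iterative in-region detection separates undersegmented berries", {
  pts <- rbind(sphere_points(1500, c(0, 0, 0), 6, seed = 15),
               sphere_points(1500, c(40, 0, 0), 8, seed = 16))
  models <- detect_berries_in_region(pts, detection_params(), seed = 17)
  expect_length(models, 2)
  radii <- sort(vapply(models, function(m) m$radius, 1.0))
  expect_equal(radii, c(6, 8), tolerance = 0.1)
  # sequential inlier removal keeps inlier sets disjoint
  expect_length(intersect(models[[1]]$inliers, models[[2]]$inliers), 0)

  # small regions terminate immediately
  expect_length(detect_berries_in_region(sphere_points(80, c(0, 0, 0), 5,
                                                       seed = 18),
                                         detection_params(), seed = 19), 0)
})

test_that("RANSAC matches the least-squares oracle on noiseless spheres", {
  for (s in 1:5) {
    r <- 1 + s * 1.5
    pts <- sphere_points(1200, c(s, -s, 2 * s), r, seed = 50 + s)
    m <- ransac_sphere(pts, detection_params(), seed = 60 + s)
    ls <- fit_sphere_least_squares(pts)
    expect_equal(m$center, ls$center, tolerance = 1e-6)
    expect_equal(m$radius, ls$radius, tolerance = 1e-6)
  }
})

test_that("overlap fraction matches closed form and Monte-Carlo oracle", {
  s <- function(c1, r) list(center = c1, radius = r)
  expect_equal(sphere_overlap_fraction(s(c(0, 0, 0), 1), s(c(0, 0, 0), 1)), 1)
  expect_equal(sphere_overlap_fraction(s(c(0, 0, 0), 1), s(c(2, 0, 0), 1)), 0)
  expect_equal(sphere_overlap_fraction(s(c(0, 0, 0), 1), s(c(5, 0, 0), 1)), 0)
  # containment: small sphere fully inside a big one
  expect_equal(sphere_overlap_fraction(s(c(0, 0, 0), 9), s(c(1, 0, 0), 2)), 1)
  # analytic lens: r1 = r2 = 1, d = 1 -> 5/16
  expect_equal(sphere_overlap_fraction(s(c(0, 0, 0), 1), s(c(1, 0, 0), 1)),
               5 / 16, tolerance = 1e-12)

  set.seed(70)
  for (i in 1:6) {
    r1 <- runif(1, 1, 9); r2 <- runif(1, 1, 9)
    d <- runif(1, 0, (r1 + r2) * 1.05)
    got <- sphere_overlap_fraction(s(c(0, 0, 0), r1), s(c(d, 0, 0), r2))
    mc <- mc_overlap_fraction(c(0, 0, 0), r1, c(d, 0, 0), r2, n = 1e6,
                              seed = 70 + i)
    expect_lt(abs(got - mc), 3e-3)
  }
})

test_that("overlap suppression keeps the best-supported representative", {
  mk <- function(center, radius, n) {
    structure(list(center = center, radius = radius, inliers = seq_len(n)),
              class = "sphere_model")
  }
  # duplicate models: only the 500-inlier one survives
  out <- resolve_overlaps(list(mk(c(0, 0, 0), 5, 300), mk(c(0, 0, 0), 5, 500)))
  expect_length(out, 1)
  expect_length(out[[1]]$inliers, 500)

  # mild overlap below the threshold: both survive
  a <- mk(c(0, 0, 0), 5, 400)
  b <- mk(c(9.2, 0, 0), 5, 300)
  expect_lt(sphere_overlap_fraction(a, b), 0.25)
  expect_length(resolve_overlaps(list(a, b)), 2)

  # chain A-B-C: B wins on support, suppresses both neighbours
  A <- mk(c(0, 0, 0), 5, 300)
  B <- mk(c(5, 0, 0), 5, 400)
  C <- mk(c(10, 0, 0), 5, 350)
  expect_equal(sphere_overlap_fraction(A, C), 0)
  out <- resolve_overlaps(list(A, B, C))
  expect_length(out, 1)
  expect_equal(out[[1]]$center, c(5, 0, 0))

  # no accepted pair exceeds the threshold (post-hoc invariant)
  set.seed(77)
  models <- lapply(1:15, function(i)
    mk(runif(3, 0, 25), runif(1, 2, 6), sample(100:600, 1)))
  out <- resolve_overlaps(models, 0.25)
  if (length(out) > 1) {
    for (i in seq_along(out)) for (j in seq_len(i - 1))
      expect_lte(sphere_overlap_fraction(out[[i]], out[[j]]), 0.25)
  }
  expect_lte(length(out), length(models))
})
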