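test_that("a single noiseless berry samples exactly on its sphere", {
  spec <- synthetic_bunch_spec(n_berries = 1, radius_range = c(8, 8),
                               points_per_berry = 5000, noise_sigma = 0,
                               include_stem = FALSE, seed = 1)
  b <- generate_bunch(spec)
  expect_equal(n_points(b$cloud), 5000)
  ctr <- as.numeric(b$truth$spheres[1, c("cx", "cy", "cz")])
  d <- sqrt(rowSums(sweep(b$cloud$points, 2, ctr, "-")^2))
  expect_lt(max(abs(d - 8)), 1e-9)
})

test_that("generation is deterministic and labels cover every point", {
  spec <- synthetic_bunch_spec(n_berries = 40, points_per_berry = 150,
                               include_hook = TRUE, seed = 77)
  b1 <- generate_bunch(spec)
  b2 <- generate_bunch(spec)
  expect_identical(b1$cloud$points, b2$cloud$points)  # bit-identical
  expect_identical(b1$truth$spheres, b2$truth$spheres)

  expect_equal(length(b1$truth$labels), n_points(b1$cloud))
  expect_equal(nrow(b1$truth$spheres), 40)
  expect_true(all(b1$truth$labels %in% c(-1L, 0L, seq_len(40))))
  expect_true(all(seq_len(40) %in% b1$truth$labels))  # every berry sampled
  expect_true(any(b1$truth$labels == 0L))   # stem points present
  expect_true(any(b1$truth$labels == -1L))  # hook points present

  # generator does not disturb the session RNG stream
  set.seed(5); before <- runif(3)
  set.seed(5); invisible(generate_bunch(spec)); after <- runif(3)
  expect_identical(before, after)
})

test_that("berry packing respects the compactness separation rule", {
  for (cp in c(0.6, 1.0)) {
    b <- generate_bunch(synthetic_bunch_spec(n_berries = 50, compactness = cp,
                                             points_per_berry = 10, seed = 3))
    s <- b$truth$spheres
    d <- as.matrix(dist(s[, c("cx", "cy", "cz")]))
    dmin <- (2 - cp) * outer(s$r, s$r, "+")
    viol <- d[upper.tri(d)] - dmin[upper.tri(dmin)]
    expect_gte(min(viol), -1e-3)
  }
  # infeasible: far too many touching berries on a short rachis
  expect_error(generate_bunch(synthetic_bunch_spec(n_berries = 400,
                                                   compactness = 1,
                                                   rachis_length = 20,
                                                   points_per_berry = 10,
                                                   seed = 4)),
               "infeasible")
})

test_that("partial scans lose points everywhere and hide buried berries", {
  base <- list(n_berries = 50, compactness = 1, rachis_length = 60,
               points_per_berry = 400, noise_sigma = 0, seed = 21)
  full <- generate_bunch(do.call(synthetic_bunch_spec, base))
  part <- generate_bunch(do.call(synthetic_bunch_spec,
                                 c(base, list(scan_mode = "partial"))))
  cf <- tabulate(full$truth$labels[full$truth$labels > 0], 50)
  cp <- tabulate(part$truth$labels[part$truth$labels > 0], 50)
  expect_true(all(cp < cf))  # strictly fewer visible points per berry
  expect_lt(sum(cp) / sum(cf), 0.6)

  # independent ray-casting oracle over the full-scan geometry (noise is 0
  # and the seed is shared, so partial points are a subset of full points):
  # a point survives iff its surface faces the camera and no other berry
  # intersects the ray towards the camera
  s <- full$truth$spheres
  lab <- full$truth$labels
  berry <- lab > 0
  pts <- full$cloud$points[berry, , drop = FALSE]
  ctr <- as.matrix(s[lab[berry], c("cx", "cy", "cz")])
  nrm <- (pts - ctr) / s$r[lab[berry]]
  visible <- nrm[, 3] > 0  # camera on +z looking along -z
  for (j in seq_len(nrow(s))) {
    w <- cbind(s$cx[j] - pts[, 1], s$cy[j] - pts[, 2], s$cz[j] - pts[, 3])
    bb <- w[, 3]  # projection on the to-camera direction (0,0,1)
    hit <- bb > 0 & (rowSums(w^2) - bb^2) < (0.999 * s$r[j])^2 &
      lab[berry] != j
    visible <- visible & !hit
  }
  oracle_counts <- tabulate(lab[berry][visible], 50)
  expect_equal(cp, oracle_counts)

  # a substantial rear layer of a dense bunch is nearly fully hidden
  expect_gte(mean(cp <= 0.10 * cf), 0.25)
  hidden <- which(cp <= 0.10 * cf)
  expect_gt(length(hidden), 0)
  expect_lt(median(s$cz[hidden]), median(s$cz))  # hidden berries sit at the rear
})

test_that("visibility agrees with an independent ray-casting oracle", {
  # single-sphere scene: back-face culling keeps exactly the camera-facing
  # hemisphere, the analytic visibility oracle
  spec <- synthetic_bunch_spec(n_berries = 1, radius_range = c(6, 6),
                               points_per_berry = 500, noise_sigma = 0,
                               include_stem = FALSE, seed = 31,
                               scan_mode = "partial",
                               view_direction = c(0, 0, -1))
  b <- generate_bunch(spec)
  # single berry, camera at +z: exactly the z-facing hemisphere survives
  ctr <- as.numeric(b$truth$spheres[1, c("cx", "cy", "cz")])
  rel <- sweep(b$cloud$points, 2, ctr, "-")
  expect_true(all(rel[, 3] > -1e-9))
  expect_equal(nrow(rel) / 500, 0.5, tolerance = 0.1)
})

test_that("detection matching is optimal, gated and order-free", {
  truth <- data.frame(id = 1:10, cx = seq(0, 90, 10), cy = 0, cz = 0, r = 5)
  mk <- function(c3, r) structure(list(center = c3, radius = r,
                                       inliers = 1:100),
                                  class = "sphere_model")
  perfect <- lapply(1:10, function(i) mk(c(truth$cx[i], 0, 0), 5))
  rep <- match_detections(truth, perfect)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  expect_equal(rep$mean_center_error, 0)
  expect_equal(rep$mean_abs_radius_error, 0)

  # two spurious detections: precision 10/12, recall 1
  spurious <- c(perfect, list(mk(c(300, 0, 0), 4), mk(c(0, 300, 0), 4)))
  rep2 <- match_detections(truth, spurious)
  expect_equal(rep2$precision, 10 / 12)
  expect_equal(rep2$recall, 1)

  # permuting detections changes nothing
  rep3 <- match_detections(truth, rev(spurious))
  expect_equal(rep3$precision, rep2$precision)
  expect_equal(sort(rep3$matches$truth_id), sort(rep2$matches$truth_id))

  # matching is optimal, not greedy-nearest: offset detections must pair
  # one-to-one with their own berries
  truth2 <- data.frame(id = 1:2, cx = c(0, 10), cy = 0, cz = 0, r = 5)
  det2 <- list(mk(c(0.9, 0, 0), 5), mk(c(10.5, 0, 0), 5))
  rep4 <- match_detections(truth2, det2)
  expect_equal(rep4$n_matched, 2L)

  # distance gate leaves far detections unmatched
  rep5 <- match_detections(truth2, list(mk(c(0, 0, 5), 5)),
                           max_center_distance = 2)
  expect_equal(rep5$n_matched, 0L)
})

test_that("bunch fixtures round-trip through PLY with sidecars", {
  b <- default_test_bunch(5, seed = 41, points_per_berry = 100)
  dir <- withr::local_tempdir()
  ply <- file.path(dir, "bunch.ply")
  write_bunch(b, ply)
  expect_true(file.exists(ply))
  expect_true(file.exists(file.path(dir, "bunch_truth.csv")))
  expect_true(file.exists(file.path(dir, "bunch_spec.json")))
  back <- read_ply(ply)
  expect_identical(back$points, b$cloud$points)
  truth <- read.csv(file.path(dir, "bunch_truth.csv"))
  expect_equal(truth$r, b$truth$spheres$r, tolerance = 1e-12)
})
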