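test_that("point_cloud validates its invariants", {
  expect_error(point_cloud(matrix(c(1, 2, NA), 1, 3)), "finite")
  expect_error(point_cloud(matrix(1, 2, 3), normals = matrix(1, 1, 3)),
               "as many rows")
  expect_error(point_cloud(matrix(1, 1, 3), normals = matrix(c(1, 1, 0), 1)),
               "unit")
  pc <- point_cloud(matrix(runif(30), 10, 3))
  expect_s3_class(pc, "point_cloud")
  expect_equal(n_points(pc), 10)
  expect_equal(n_points(point_cloud(matrix(numeric(0), ncol = 3))), 0)
})

test_that("ascii PLY reads back simple vertex lists", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 3",
               "property float x", "property float y", "property float z",
               "end_header", "0 0 0", "1 0 0", "0 1 0"), path)
  pc <- read_ply(path)
  expect_equal(pc$points, rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
})

test_that("write_ply / read_ply round-trips coordinates, normals, colors", {
  set.seed(42)
  pts <- matrix(runif(3000, -50, 50), ncol = 3)
  nrm <- matrix(rnorm(3000), ncol = 3)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  col <- matrix(sample(0:255, 3000, TRUE), ncol = 3)
  pc <- point_cloud(pts, normals = nrm, colors = col)

  bin <- withr::local_tempfile(fileext = ".ply")
  write_ply(pc, bin, binary = TRUE)
  back <- read_ply(bin)
  expect_identical(back$points, pts)      # bit-exact: doubles on disk
  expect_equal(back$normals, nrm, tolerance = 1e-12)
  expect_equal(back$colors, col, ignore_attr = TRUE)

  asc <- withr::local_tempfile(fileext = ".ply")
  write_ply(pc, asc, binary = FALSE)
  back2 <- read_ply(asc)
  expect_equal(back2$points, pts, tolerance = 1e-15)

  # empty cloud round trip
  e <- withr::local_tempfile(fileext = ".ply")
  write_ply(point_cloud(matrix(numeric(0), ncol = 3)), e)
  expect_equal(n_points(read_ply(e)), 0)
  expect_true(any(grepl("element vertex 0", readLines(e, n = 10))))
})

test_that("faces are dropped; vertex count matches a reference parser", {
  path <- withr::local_tempfile(fileext = ".ply")
  write_face_ply(path)
  pc <- read_ply(path)
  expect_equal(n_points(pc), 4)
  expect_equal(pc$points[4, ], c(0, 0, 10))

  ref <- tryCatch(system2("python", c("-c", shQuote(sprintf(
    "import trimesh; m = trimesh.load('%s', process=False); print(len(m.vertices))",
    path))), stdout = TRUE, stderr = FALSE), warning = function(w) NULL,
    error = function(e) NULL)
  if (!is.null(ref) && length(ref))
    expect_equal(as.integer(ref[length(ref)]), 4L)
})

test_that("malformed and unsupported PLY inputs fail with clear errors", {
  expect_error(read_ply(file.path(tempdir(), "nope.ply")), "not found")
  p <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format binary_big_endian 1.0", "element vertex 1",
               "property float x", "property float y", "property float z",
               "end_header"), p)
  expect_error(read_ply(p), "binary_big_endian")

  writeLines(c("ply", "format ascii 1.0", "element vertex 3",
               "property float x", "property float y", "property float z",
               "end_header", "0 0 0", "1 0"), p)
  expect_error(read_ply(p), "truncated|fields")

  writeLines(c("ply", "format ascii 1.0", "element vertex 2",
               "property float x", "property float y", "property float z",
               "end_header", "0 0 0", "1 0 zz 9"), p)
  expect_error(read_ply(p), "line 2")
})

test_that("binary PLY with uchar colors and float32 coordinates parses", {
  # hand-assembled little-endian payload: x,y,z float32 + rgb uchar
  p <- withr::local_tempfile(fileext = ".ply")
  con <- file(p, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0", "element vertex 2",
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green",
               "property uchar blue", "end_header"), con)
  for (row in list(list(c(1.5, 2.5, -3.5), c(10L, 20L, 30L)),
                   list(c(0, 4, 8), c(255L, 0L, 128L)))) {
    writeBin(row[[1]], con, size = 4, endian = "little")
    writeBin(as.raw(row[[2]]), con)
  }
  close(con)
  pc <- read_ply(p)
  expect_equal(pc$points, rbind(c(1.5, 2.5, -3.5), c(0, 4, 8)))
  expect_equal(pc$colors, rbind(c(10L, 20L, 30L), c(255L, 0L, 128L)),
               ignore_attr = TRUE)
})

test_that("voxel downsampling matches a brute-force occupancy oracle", {
  # two close points collapse to their centroid
  pc <- point_cloud(rbind(c(0.1, 0.1, 0.1), c(0.2, 0.1, 0.1)))
  out <- voxel_downsample(pc, 0.4)
  expect_equal(n_points(out), 1)
  expect_equal(out$points[1, ], c(0.15, 0.1, 0.1))

  # grid-aligned points all survive
  g <- as.matrix(expand.grid(x = 0:4, y = 0:4, z = 0:4)) + 0.05
  expect_equal(n_points(voxel_downsample(point_cloud(g), 0.4)), nrow(g))

  # random cloud: output count equals brute-force voxel occupancy
  set.seed(11)
  pts <- matrix(runif(30000, 0, 50), ncol = 3)
  res <- 0.4
  key <- paste(floor(pts[, 1] / res), floor(pts[, 2] / res),
               floor(pts[, 3] / res))
  out <- voxel_downsample(point_cloud(pts), res)
  expect_equal(n_points(out), length(unique(key)))

  # idempotence and monotonicity
  again <- voxel_downsample(out, res)
  expect_equal(n_points(again), n_points(out))
  expect_lte(n_points(out), nrow(pts))
  # resolution -> 0 keeps all distinct points
  expect_equal(n_points(voxel_downsample(point_cloud(pts), 1e-6)), nrow(pts))
})

test_that("normal estimation recovers analytic plane and sphere normals", {
  pc <- point_cloud(plane_points(400, y = 0, seed = 3))
  pc <- estimate_normals(pc, k = 12)
  expect_true(all(abs(abs(pc$normals[, 2]) - 1) < 1e-6))
  expect_true(all(pc$curvature < 1e-9))

  center <- c(5, -3, 2)
  sp <- point_cloud(fib_sphere(3000, center, 8))
  sp <- estimate_normals(sp, k = 20)
  radial <- sweep(sp$points, 2, center, "-")
  radial <- radial / sqrt(rowSums(radial^2))
  ang <- acos(pmin(1, abs(rowSums(sp$normals * radial)))) * 180 / pi
  expect_lt(max(ang), 2)
  # outward orientation: positive dot with the radial direction
  expect_true(all(rowSums(sp$normals * radial) > 0))
  # curvature on the plane is below curvature on the sphere
  expect_lt(max(pc$curvature), min(sp$curvature[sp$curvature > 0]) + 1e-9)

  expect_error(estimate_normals(point_cloud(matrix(runif(9), 3, 3)), k = 5),
               "k\\+1")
})
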