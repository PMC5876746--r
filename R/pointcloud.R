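#' Point cloud container
#'
#' A `point_cloud` holds the vertices of one scan: an `n x 3` matrix of
#' coordinates in millimetres, with the vertical axis along y (bunches hang
#' along y, so bunch length is measured on this axis), and optionally
#' per-point unit normals, RGB colors and a PCA curvature score.
#'
#' @param points numeric matrix with 3 columns (x, y, z), in mm.
#' @param normals optional numeric matrix of unit normals, same dimensions.
#' @param colors optional integer matrix of RGB triples in 0--255.
#' @param curvature optional numeric vector of per-point curvature scores.
#' @return An object of class `point_cloud`.
#' @examples
#' pc <- point_cloud(matrix(rnorm(30), ncol = 3))
#' n_points(pc)
#' @export
point_cloud <- function(points, normals = NULL, colors = NULL,
                        curvature = NULL) {
  points <- as_coord_matrix(points, "points")
  if (nrow(points) && !all(is.finite(points)))
    stop("point coordinates must be finite (no NA/NaN/Inf)")
  n <- nrow(points)
  if (!is.null(normals)) {
    normals <- as_coord_matrix(normals, "normals")
    if (nrow(normals) != n)
      stop("normals must have exactly as many rows as points")
    nrm <- sqrt(rowSums(normals^2))
    if (n && any(abs(nrm - 1) > 1e-6))
      stop("normals must be unit vectors (norm within 1e-6 of 1)")
  }
  if (!is.null(colors)) {
    colors <- as_coord_matrix(colors, "colors")
    if (nrow(colors) != n)
      stop("colors must have exactly as many rows as points")
    if (n && (any(colors < 0) || any(colors > 255)))
      stop("colors must be RGB values in 0..255")
    storage.mode(colors) <- "integer"
  }
  if (!is.null(curvature)) {
    curvature <- as.numeric(curvature)
    if (length(curvature) != n)
      stop("curvature must have one value per point")
  }
  structure(list(points = points, normals = normals, colors = colors,
                 curvature = curvature),
            class = "point_cloud")
}

as_coord_matrix <- function(x, what) {
  x <- as.matrix(x)
  if (length(x) == 0) x <- matrix(numeric(0), ncol = 3)
  if (ncol(x) != 3) stop(sprintf("%s must have 3 columns", what))
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' Number of points in a cloud
#' @param cloud a [point_cloud()].
#' @return Integer point count.
#' @export
n_points <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  nrow(cloud$points)
}

#' @export
print.point_cloud <- function(x, ...) {
  n <- n_points(x)
  cat(sprintf("point_cloud: %d points", n))
  extras <- c(if (!is.null(x$normals)) "normals",
              if (!is.null(x$colors)) "colors",
              if (!is.null(x$curvature)) "curvature")
  if (length(extras)) cat(" (+", paste(extras, collapse = ", "), ")", sep = "")
  cat("\n")
  if (n) {
    rng <- apply(x$points, 2, range)
    cat(sprintf("  extent [mm]: x %.1f..%.1f  y %.1f..%.1f  z %.1f..%.1f\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

#' Voxel-grid downsampling
#'
#' Reduces a high-resolution scan to one representative point per occupied
#' cubic voxel: each point is binned by `floor(coordinate / resolution)` on
#' every axis (grid origin at 0,0,0) and each occupied voxel is replaced by
#' the centroid of its members. Normals are averaged and renormalised,
#' colors averaged and rounded. The default working resolution of the berry
#' detector is 0.4 mm.
#'
#' @param cloud a [point_cloud()].
#' @param resolution voxel edge length in mm (> 0).
#' @return A `point_cloud` with at most as many points as the input, ordered
#'   by voxel index.
#' @examples
#' pc <- point_cloud(matrix(runif(300, 0, 10), ncol = 3))
#' voxel_downsample(pc, 1.0)
#' @export
voxel_downsample <- function(cloud, resolution) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0)
    stop("resolution must be a single positive number (mm)")
  n <- n_points(cloud)
  if (n == 0) return(cloud)
  dt <- data.table::data.table(
    ix = floor(cloud$points[, 1] / resolution),
    iy = floor(cloud$points[, 2] / resolution),
    iz = floor(cloud$points[, 3] / resolution),
    x = cloud$points[, 1], y = cloud$points[, 2], z = cloud$points[, 3])
  has_nrm <- !is.null(cloud$normals)
  has_col <- !is.null(cloud$colors)
  if (has_nrm) dt[, c("nx", "ny", "nz") := list(cloud$normals[, 1],
                                                cloud$normals[, 2],
                                                cloud$normals[, 3])]
  if (has_col) dt[, c("r", "g", "b") := list(cloud$colors[, 1],
                                             cloud$colors[, 2],
                                             cloud$colors[, 3])]
  agg <- dt[, lapply(.SD, mean), by = c("ix", "iy", "iz")]
  data.table::setorderv(agg, c("ix", "iy", "iz"))
  pts <- as.matrix(agg[, c("x", "y", "z")])
  normals <- NULL
  if (has_nrm) {
    normals <- as.matrix(agg[, c("nx", "ny", "nz")])
    len <- sqrt(rowSums(normals^2))
    len[len < 1e-12] <- 1
    normals <- normals / len
  }
  colors <- NULL
  if (has_col) colors <- round(as.matrix(agg[, c("r", "g", "b")]))
  point_cloud(pts, normals = normals, colors = colors)
}

#' Estimate surface normals and curvature by local PCA
#'
#' For every point the covariance of its k nearest neighbours (plus itself)
#' is decomposed; the eigenvector of the smallest eigenvalue is the surface
#' normal and `lambda_min / (lambda_1 + lambda_2 + lambda_3)` the curvature
#' score (0 on a plane, up to 1/3 for isotropic noise). Normals are oriented
#' away from the local neighbourhood centroid, which points outward on the
#' convex berry surfaces the detector targets.
#'
#' @param cloud a [point_cloud()] with at least `k + 1` points.
#' @param k neighbourhood size (>= 3); default 30.
#' @return The cloud with `normals` and `curvature` filled in.
#' @examples
#' pc <- point_cloud(cbind(runif(200), 0, runif(200)))
#' pc <- estimate_normals(pc, k = 10)
#' head(pc$normals)
#' @export
estimate_normals <- function(cloud, k = 30) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (k < 3) stop("k must be >= 3")
  n <- n_points(cloud)
  if (n < k + 1) stop(sprintf("need at least k+1 = %d points, got %d", k + 1, n))
  nn <- cpp_knn(cloud$points, as.integer(k))
  res <- cpp_pca_normals(cloud$points, nn)
  cloud$normals <- res$normals
  cloud$curvature <- as.numeric(res$curvature)
  cloud
}

#' K-nearest-neighbour indices
#'
#' Thin wrapper over the package's kd-tree, exposed because segmentation and
#' diagnostics share the same neighbourhood graph.
#'
#' @param cloud a [point_cloud()].
#' @param k neighbour count.
#' @return Integer matrix `n x k` of 1-based row indices, nearest first;
#'   the point itself is excluded.
#' @export
knn_indices <- function(cloud, k) {
  stopifnot(inherits(cloud, "point_cloud"))
  cpp_knn(cloud$points, as.integer(k))
}
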