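#' Berry detection parameters
#'
#' Gates and settings of the RANSAC sphere detector. The defaults follow the
#' published tool configuration for dense bunch scans: accepted berry radii
#' between 1 and 9 mm, at least 100 supporting points per sphere, and a
#' working resolution of 0.4 mm which also sets the inlier distance band.
#'
#' @param min_radius minimal accepted sphere radius, mm.
#' @param max_radius maximal accepted sphere radius, mm.
#' @param min_supporters minimal number of inliers for an accepted sphere.
#' @param inlier_distance half-width of the surface band counting a point as
#'   an inlier, mm.
#' @param ransac_iterations minimal-sample draws per RANSAC run.
#' @param overlap_threshold pairwise overlap fraction above which the less
#'   supported of two spheres is suppressed.
#' @param random_seed integer seed making detection deterministic.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(min_radius = 1, max_radius = 9,
                             min_supporters = 100, inlier_distance = 0.4,
                             ransac_iterations = 1000,
                             overlap_threshold = 0.25, random_seed = 1L) {
  if (min_radius <= 0 || min_radius >= max_radius)
    stop("need 0 < min_radius < max_radius")
  if (min_supporters < 4) stop("min_supporters must be >= 4")
  if (inlier_distance <= 0) stop("inlier_distance must be > 0")
  if (overlap_threshold <= 0 || overlap_threshold >= 1)
    stop("overlap_threshold must be in (0, 1)")
  structure(list(min_radius = min_radius, max_radius = max_radius,
                 min_supporters = as.integer(min_supporters),
                 inlier_distance = inlier_distance,
                 ransac_iterations = as.integer(ransac_iterations),
                 overlap_threshold = overlap_threshold,
                 random_seed = as.integer(random_seed)),
            class = "detection_params")
}

new_sphere_model <- function(center, radius, inliers) {
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 inliers = as.integer(inliers)),
            class = "sphere_model")
}

#' @export
print.sphere_model <- function(x, ...) {
  cat(sprintf("sphere_model: center (%.2f, %.2f, %.2f) mm, radius %.2f mm, %d inliers\n",
              x$center[1], x$center[2], x$center[3], x$radius,
              length(x$inliers)))
  invisible(x)
}

#' Sphere through four points
#'
#' Solves the 4x4 linear system of the algebraic sphere equation; the minimal
#' solver inside RANSAC. Coplanar or cocircular samples are degenerate and
#' return `NULL` (a normal outcome, not an error).
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates.
#' @return `list(center, radius)` or `NULL` when degenerate.
#' @examples
#' fit_sphere_minimal(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1))
#' @export
fit_sphere_minimal <- function(p1, p2, p3, p4) {
  pts <- rbind(p1, p2, p3, p4)
  storage.mode(pts) <- "double"
  cpp_sphere_from4(pts)
}

#' Algebraic least-squares sphere fit
#'
#' Minimises the linearised residual
#' `sum((|p|^2 - 2 p.c - (r^2 - |c|^2))^2)` over all points; used to refine
#' the best RANSAC hypothesis on its consensus set. The system stays full
#' rank on partial coverage (e.g. a hemisphere from a single-side scan).
#'
#' @param points numeric matrix (n x 3), n >= 4, not all coplanar.
#' @return `list(center, radius)` or `NULL` when rank deficient.
#' @export
fit_sphere_least_squares <- function(points) {
  points <- as_coord_matrix(points, "points")
  if (nrow(points) < 4) stop("at least 4 points required")
  cpp_sphere_lsq(points)
}

#' RANSAC sphere detection on one point set
#'
#' Draws up to `ransac_iterations` minimal 4-point samples, skips degenerate
#' samples and radii outside the berry gates, scores each hypothesis by the
#' number of points within `inlier_distance` of its surface, refines the best
#' hypothesis by least squares on its inliers and recounts once. The refined
#' model is returned only if its radius lies within the gates and its inlier
#' count reaches `min_supporters`.
#'
#' @param points numeric matrix (n x 3) in mm.
#' @param params a [detection_params()].
#' @param seed integer seed for this run; defaults to `params$random_seed`.
#' @return A `sphere_model` (inliers are 1-based row indices into `points`)
#'   or `NULL`.
#' @export
ransac_sphere <- function(points, params = detection_params(),
                          seed = params$random_seed) {
  points <- as_coord_matrix(points, "points")
  if (nrow(points) < params$min_supporters) return(NULL)
  res <- cpp_ransac_sphere(points, params$min_radius, params$max_radius,
                           params$inlier_distance, params$min_supporters,
                           params$ransac_iterations, as.integer(seed))
  if (is.null(res)) return(NULL)
  new_sphere_model(res$center, res$radius, res$inliers)
}

#' Iterative berry detection within one region
#'
#' Handles undersegmentation: RANSAC is run on the region, the accepted
#' model's inliers are removed, and the remainder is re-used until fewer than
#' `min_supporters` points remain or no acceptable model is found.
#'
#' @param points numeric matrix (n x 3) of the region's coordinates.
#' @param params a [detection_params()].
#' @param seed integer base seed; each pass derives its own stream.
#' @return List of `sphere_model`s with pairwise disjoint inlier sets
#'   (indices into `points`).
#' @export
detect_berries_in_region <- function(points, params = detection_params(),
                                     seed = params$random_seed) {
  points <- as_coord_matrix(points, "points")
  remaining <- seq_len(nrow(points))
  models <- list()
  pass <- 0L
  while (length(remaining) >= params$min_supporters) {
    pass <- pass + 1L
    model <- ransac_sphere(points[remaining, , drop = FALSE], params,
                           seed = (seed + 7919L * pass) %% .Machine$integer.max)
    if (is.null(model)) break
    model$inliers <- remaining[model$inliers]
    models[[length(models) + 1L]] <- model
    remaining <- setdiff(remaining, model$inliers)
  }
  models
}

#' Overlap fraction of two spheres
#'
#' Closed-form spherical-lens intersection volume, normalised by the volume
#' of the smaller sphere: 0 for disjoint or tangent spheres, 1 when one
#' sphere contains the other. This is the measure the duplicate-suppression
#' step thresholds at 25%.
#'
#' @param s1,s2 `sphere_model`s, or lists with `center` and `radius`.
#' @return Overlap fraction in `[0, 1]`.
#' @examples
#' a <- list(center = c(0, 0, 0), radius = 1)
#' b <- list(center = c(1, 0, 0), radius = 1)
#' sphere_overlap_fraction(a, b)  # 5/16
#' @export
sphere_overlap_fraction <- function(s1, s2) {
  r1 <- s1$radius; r2 <- s2$radius
  if (r1 <= 0 || r2 <= 0) stop("radii must be positive")
  d <- sqrt(sum((s1$center - s2$center)^2))
  if (d >= r1 + r2) return(0)
  vmin <- 4 / 3 * pi * min(r1, r2)^3
  if (d <= abs(r1 - r2)) return(1)  # smaller sphere contained
  lens <- pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * r1 - 3 * r1^2 + 2 * d * r2 + 6 * r1 * r2 - 3 * r2^2) /
    (12 * d)
  min(max(lens / vmin, 0), 1)
}

#' Suppress overlapping duplicate detections
#'
#' Oversegmentation can yield several sphere models for one berry. Models are
#' ranked by inlier count (ties: larger radius, then lexicographic center)
#' and accepted greedily; a model is dropped when its overlap fraction with
#' any already-accepted model exceeds `overlap_threshold`, so of two heavily
#' overlapping models only the better-supported one survives.
#'
#' @param models list of `sphere_model`s.
#' @param overlap_threshold maximal tolerated pairwise overlap fraction.
#' @return The accepted subset, in acceptance order.
#' @export
resolve_overlaps <- function(models, overlap_threshold = 0.25) {
  if (!length(models)) return(list())
  cnt <- vapply(models, function(m) length(m$inliers), 1L)
  rad <- vapply(models, function(m) m$radius, 1.0)
  cx <- vapply(models, function(m) m$center[1], 1.0)
  cy <- vapply(models, function(m) m$center[2], 1.0)
  cz <- vapply(models, function(m) m$center[3], 1.0)
  ord <- order(-cnt, -rad, cx, cy, cz)
  accepted <- list()
  for (i in ord) {
    cand <- models[[i]]
    ok <- TRUE
    for (a in accepted) {
      if (sphere_overlap_fraction(cand, a) > overlap_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) accepted[[length(accepted) + 1L]] <- cand
  }
  accepted
}

#' Detected spheres as a data frame
#'
#' @param models list of `sphere_model`s.
#' @return data.frame with columns `cx`, `cy`, `cz`, `radius`, `n_inliers`.
#' @export
sphere_models_df <- function(models) {
  data.frame(
    cx = vapply(models, function(m) m$center[1], 1.0),
    cy = vapply(models, function(m) m$center[2], 1.0),
    cz = vapply(models, function(m) m$center[3], 1.0),
    radius = vapply(models, function(m) m$radius, 1.0),
    n_inliers = vapply(models, function(m) length(m$inliers), 1L))
}

#' Export detected berries as a PLY of sampled sphere surfaces
#'
#' Diagnostic mirror of the tool's viewport: each accepted sphere is sampled
#' on a deterministic spiral lattice and written as a green point set.
#'
#' @param models list of `sphere_model`s.
#' @param path output PLY path.
#' @param points_per_sphere lattice points per sphere surface.
#' @return Invisibly, `path`.
#' @export
export_spheres_ply <- function(models, path, points_per_sphere = 400) {
  pts <- do.call(rbind, lapply(models, function(m) {
    i <- seq_len(points_per_sphere)
    # Fibonacci sphere lattice: deterministic, near-uniform
    z <- 1 - 2 * (i - 0.5) / points_per_sphere
    phi <- i * pi * (3 - sqrt(5))
    rho <- sqrt(pmax(0, 1 - z^2))
    cbind(m$center[1] + m$radius * rho * cos(phi),
          m$center[2] + m$radius * z,
          m$center[3] + m$radius * rho * sin(phi))
  }))
  if (is.null(pts)) pts <- matrix(numeric(0), ncol = 3)
  colors <- matrix(rep(c(0L, 200L, 0L), each = nrow(pts)), ncol = 3)
  write_ply(point_cloud(pts, colors = colors), path)
}
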