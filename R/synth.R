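# Ground-truthed synthetic grape bunches. The generator emulates the data
# properties of dense structured-light scans: spherical berries with radii in
# the published diameter range, surface sampling at a density comparable to a
# 0.4 mm mesh, sub-millimetre Gaussian sensor noise, rachis/pedicel and hook
# structure points, and single-side (partial) scans with view-dependent
# occlusion.

#' Synthetic bunch specification
#'
#' Generative parameters plus the seed that makes a bunch reproducible.
#' Berry centers are placed around a vertical (y-axis) rachis and relaxed
#' pairwise until no two centers are closer than
#' `(2 - compactness) * (r_i + r_j)`: `compactness = 1` gives touching
#' berries (dense bunch), smaller values give looser bunches.
#'
#' @param n_berries number of berries (>= 1).
#' @param radius_range min/max berry radius in mm, drawn uniformly; the
#'   default 4.6--8.45 mm matches berry diameters of 9.2--16.9 mm.
#' @param rachis_length vertical extent available for berry insertion, mm.
#' @param compactness packing parameter in (0, 1]; 1 = berries touching.
#' @param points_per_berry surface samples per berry (area-uniform).
#' @param noise_sigma isotropic Gaussian sensor noise, mm.
#' @param include_stem sample rachis and pedicel cylinders.
#' @param include_hook sample a mounting-hook cylinder above the bunch.
#' @param scan_mode `"full"` (360 degree) or `"partial"` (single side with
#'   back-face culling and sphere occlusion).
#' @param view_direction viewing direction of the partial scan (the way the
#'   camera looks); default `c(0, 0, -1)`, camera on the +z side.
#' @param seed integer seed; the whole generation is deterministic given it.
#' @return A list of class `synthetic_bunch_spec`.
#' @export
synthetic_bunch_spec <- function(n_berries = 100,
                                 radius_range = c(4.6, 8.45),
                                 rachis_length = 140,
                                 compactness = 0.9,
                                 points_per_berry = 1000,
                                 noise_sigma = 0.1,
                                 include_stem = TRUE,
                                 include_hook = FALSE,
                                 scan_mode = c("full", "partial"),
                                 view_direction = c(0, 0, -1),
                                 seed = 1L) {
  scan_mode <- match.arg(scan_mode)
  if (n_berries < 1) stop("n_berries must be >= 1")
  if (length(radius_range) != 2 || radius_range[1] > radius_range[2])
    stop("radius_range must be c(min, max)")
  if (radius_range[1] < 1 || radius_range[2] > 9)
    stop("radii must stay within [1, 9] mm to match the detector gates")
  if (compactness <= 0 || compactness > 1)
    stop("compactness must be in (0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (points_per_berry < 1) stop("points_per_berry must be >= 1")
  vd <- view_direction / sqrt(sum(view_direction^2))
  structure(list(n_berries = as.integer(n_berries),
                 radius_range = as.numeric(radius_range),
                 rachis_length = rachis_length, compactness = compactness,
                 points_per_berry = as.integer(points_per_berry),
                 noise_sigma = noise_sigma,
                 include_stem = isTRUE(include_stem),
                 include_hook = isTRUE(include_hook),
                 scan_mode = scan_mode, view_direction = vd,
                 seed = as.integer(seed)),
            class = "synthetic_bunch_spec")
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# pairwise push-apart relaxation; centers clamped vertically to the rachis
relax_centers <- function(centers, radii, compactness, rachis_length,
                          max_iter = 300, tol = 1e-3) {
  n <- nrow(centers)
  if (n == 1) return(centers)
  dmin <- (2 - compactness) * outer(radii, radii, "+")
  diag(dmin) <- 0
  for (iter in seq_len(max_iter)) {
    d <- as.matrix(stats::dist(centers))
    viol <- which(d < dmin - tol & upper.tri(d), arr.ind = TRUE)
    if (!nrow(viol)) return(centers)
    for (v in seq_len(nrow(viol))) {
      i <- viol[v, 1]; j <- viol[v, 2]
      dir <- centers[j, ] - centers[i, ]
      len <- sqrt(sum(dir^2))
      if (len < 1e-9) {  # coincident: split along a fixed direction
        dir <- c(1, 0, 0); len <- 1
      }
      push <- (dmin[i, j] - len) / 2 * 1.05
      centers[i, ] <- centers[i, ] - dir / len * push
      centers[j, ] <- centers[j, ] + dir / len * push
    }
    centers[, 2] <- pmin(pmax(centers[, 2], 0), rachis_length)
  }
  d <- as.matrix(stats::dist(centers))
  if (any(d < dmin - tol & upper.tri(d)))
    stop(paste("packing infeasible: could not separate berries;",
               "reduce n_berries or compactness, or increase rachis_length"))
  centers
}

sample_sphere_surface <- function(center, radius, n) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  len <- sqrt(rowSums(v^2))
  len[len < 1e-12] <- 1
  dirs <- v / len
  list(points = sweep(dirs * radius, 2, center, "+"), normals = dirs)
}

# points on the lateral surface of a cylinder from a to b
sample_cylinder <- function(a, b, radius, density_mm2) {
  axis <- b - a
  h <- sqrt(sum(axis^2))
  if (h < 1e-9) return(NULL)
  axis <- axis / h
  n <- max(1L, round(2 * pi * radius * h * density_mm2))
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  w <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  t <- runif(n, 0, h)
  th <- runif(n, 0, 2 * pi)
  radial <- outer(cos(th), u) + outer(sin(th), w)
  pts <- matrix(a, n, 3, byrow = TRUE) + outer(t, axis) + radius * radial
  list(points = pts, normals = radial)
}

#' Generate a ground-truthed synthetic bunch point cloud
#'
#' Builds berry spheres around a vertical rachis, relaxes the packing,
#' samples every surface area-uniformly, optionally adds rachis/pedicel and
#' hook points, applies the partial-scan visibility model (back-face culling
#' plus occlusion by nearer berries along the view ray) and finally adds
#' isotropic Gaussian noise. Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_bunch_spec()].
#' @return List with `cloud` (a [point_cloud()]) and `truth`: a list holding
#'   `spheres` (data.frame `id`, `cx`, `cy`, `cz`, `r`), `labels` (per-point
#'   integer: berry id, 0 = stem, -1 = hook) and the generating `spec`.
#' @export
generate_bunch <- function(spec) {
  stopifnot(inherits(spec, "synthetic_bunch_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_berries
    radii <- runif(n, spec$radius_range[1], spec$radius_range[2])
    rho_max <- 15 + 45 * (1 - spec$compactness)
    rho <- sqrt(runif(n)) * rho_max
    phi <- runif(n, 0, 2 * pi)
    centers <- cbind(rho * cos(phi),
                     runif(n, 0, spec$rachis_length),
                     rho * sin(phi))
    centers <- relax_centers(centers, radii, spec$compactness,
                             spec$rachis_length)

    pts <- vector("list", n + 2L)
    nrm <- vector("list", n + 2L)
    lab <- vector("list", n + 2L)
    for (i in seq_len(n)) {
      s <- sample_sphere_surface(centers[i, ], radii[i],
                                 spec$points_per_berry)
      pts[[i]] <- s$points
      nrm[[i]] <- s$normals
      lab[[i]] <- rep.int(i, nrow(s$points))
    }
    # match berry surface density so stem points neither dominate nor vanish
    density <- spec$points_per_berry / (4 * pi * mean(radii)^2)
    if (spec$include_stem) {
      ylo <- min(centers[, 2]) - 5
      yhi <- spec$rachis_length + 10
      parts <- list(sample_cylinder(c(0, ylo, 0), c(0, yhi, 0), 1.5, density))
      for (i in seq_len(n))
        parts[[i + 1L]] <- sample_cylinder(c(0, centers[i, 2], 0),
                                           centers[i, ], 0.8, density)
      parts <- parts[!vapply(parts, is.null, TRUE)]
      pts[[n + 1L]] <- do.call(rbind, lapply(parts, `[[`, "points"))
      nrm[[n + 1L]] <- do.call(rbind, lapply(parts, `[[`, "normals"))
      lab[[n + 1L]] <- rep.int(0L, nrow(pts[[n + 1L]]))
    }
    if (spec$include_hook) {
      top <- spec$rachis_length + 10
      hook <- sample_cylinder(c(0, top, 0), c(0, top + 25, 0), 2, density)
      pts[[n + 2L]] <- hook$points
      nrm[[n + 2L]] <- hook$normals
      lab[[n + 2L]] <- rep.int(-1L, nrow(hook$points))
    }
    points <- do.call(rbind, pts[!vapply(pts, is.null, TRUE)])
    normals <- do.call(rbind, nrm[!vapply(nrm, is.null, TRUE)])
    labels <- unlist(lab[!vapply(lab, is.null, TRUE)])

    if (spec$scan_mode == "partial") {
      keep <- partial_scan_visible(points, normals, labels, centers, radii,
                                   spec$view_direction)
      points <- points[keep, , drop = FALSE]
      labels <- labels[keep]
    }
    if (spec$noise_sigma > 0)
      points <- points + matrix(rnorm(length(points), 0, spec$noise_sigma),
                                ncol = 3)
    truth <- list(
      spheres = data.frame(id = seq_len(n), cx = centers[, 1],
                           cy = centers[, 2], cz = centers[, 3], r = radii),
      labels = labels, spec = spec)
    list(cloud = point_cloud(points), truth = truth)
  })
}

# visibility of each point under single-side scanning: the surface must face
# the camera (back-face culling) and the ray from the point to the camera
# must not pass through any other berry sphere
partial_scan_visible <- function(points, normals, labels, centers, radii,
                                 view_direction) {
  to_cam <- -view_direction   # unit vector from surface towards the camera
  facing <- drop(normals %*% to_cam) > 0
  occluded <- rep(FALSE, nrow(points))
  for (j in seq_len(nrow(centers))) {
    w <- sweep(-points, 2, centers[j, ], "+")   # center_j - p
    b <- drop(w %*% to_cam)
    d2 <- rowSums(w^2) - b^2
    hit <- b > 0 & d2 < (0.999 * radii[j])^2 & labels != j
    occluded <- occluded | hit
  }
  facing & !occluded
}

#' Write a synthetic bunch to disk
#'
#' Emits the PLY cloud plus a ground-truth CSV (`id, cx, cy, cz, r`) and a
#' JSON sidecar with the generating parameters, so a fixture can be
#' regenerated or audited.
#'
#' @param bunch result of [generate_bunch()].
#' @param path output PLY path; the CSV and JSON sidecars take the same stem.
#' @param binary passed to [write_ply()].
#' @return Invisibly, `path`.
#' @export
write_bunch <- function(bunch, path, binary = TRUE) {
  write_ply(bunch$cloud, path, binary = binary)
  stem <- sub("\\.ply$", "", path)
  write.table(bunch$truth$spheres, paste0(stem, "_truth.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  spec <- bunch$truth$spec
  spec_out <- unclass(spec)
  jsonlite::write_json(spec_out, paste0(stem, "_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Match detected spheres against ground truth
#'
#' Minimum-cost one-to-one assignment (Hungarian algorithm) between truth
#' spheres and detections on center distance; pairs farther apart than
#' `max_center_distance` stay unmatched. The report is invariant to the
#' order of the detections.
#'
#' @param truth the `truth` element of [generate_bunch()] output, or a
#'   data.frame with columns `cx`, `cy`, `cz`, `r`.
#' @param models list of `sphere_model`s.
#' @param max_center_distance matching gate, mm (default 2).
#' @return List with `n_truth`, `n_detected`, `n_matched`, `precision`,
#'   `recall`, `mean_center_error`, `mean_abs_radius_error` and a `matches`
#'   data.frame (`truth_id`, `model_id`, `center_error`, `radius_error`).
#' @export
match_detections <- function(truth, models, max_center_distance = 2) {
  spheres <- if (is.data.frame(truth)) truth else truth$spheres
  nt <- nrow(spheres)
  nd <- length(models)
  empty <- list(n_truth = nt, n_detected = nd, n_matched = 0L,
                precision = if (nd) 0 else NA_real_,
                recall = if (nt) 0 else NA_real_,
                mean_center_error = NA_real_,
                mean_abs_radius_error = NA_real_,
                matches = data.frame(truth_id = integer(0),
                                     model_id = integer(0),
                                     center_error = numeric(0),
                                     radius_error = numeric(0)))
  if (nt == 0 || nd == 0) return(empty)
  det <- sphere_models_df(models)
  cost <- outer(seq_len(nt), seq_len(nd), function(i, j) {
    sqrt((spheres$cx[i] - det$cx[j])^2 + (spheres$cy[i] - det$cy[j])^2 +
           (spheres$cz[i] - det$cz[j])^2)
  })
  big <- max_center_distance * 1e6 + max(cost)  # forbids gate-violating pairs
  cost_cap <- ifelse(cost > max_center_distance, big, cost)
  if (nt <= nd) {
    assign_col <- cpp_hungarian(cost_cap)
    pairs <- cbind(truth = seq_len(nt), det = assign_col)
  } else {
    assign_col <- cpp_hungarian(t(cost_cap))
    pairs <- cbind(truth = assign_col, det = seq_len(nd))
  }
  dist <- cost[pairs]
  keep <- dist <= max_center_distance
  pairs <- pairs[keep, , drop = FALSE]
  dist <- dist[keep]
  rerr <- det$radius[pairs[, 2]] - spheres$r[pairs[, 1]]
  nm <- nrow(pairs)
  list(n_truth = nt, n_detected = nd, n_matched = nm,
       precision = nm / nd, recall = nm / nt,
       mean_center_error = if (nm) mean(dist) else NA_real_,
       mean_abs_radius_error = if (nm) mean(abs(rerr)) else NA_real_,
       matches = data.frame(truth_id = pairs[, 1], model_id = pairs[, 2],
                            center_error = dist, radius_error = rerr))
}
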