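#' 3D convex hull volume
#'
#' Quickhull over a point set; used for the convex-hull trait (volume of the
#' hull of all points lying inside a detected berry). Degenerate inputs
#' (fewer than 4 points, collinear or coplanar sets) return 0 with a
#' warning.
#'
#' @param points numeric matrix (n x 3).
#' @return Hull volume in the cube of the input unit (mm^3 for mm input).
#' @examples
#' cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
#' convex_hull_volume(cube)  # 1
#' @export
convex_hull_volume <- function(points) {
  points <- as_coord_matrix(points, "points")
  if (nrow(points) < 4) {
    warning("fewer than 4 points: hull volume set to 0")
    return(0)
  }
  vol <- cpp_convex_hull_volume(points)
  if (vol == 0) warning("degenerate (coplanar/collinear) points: hull volume 0")
  vol
}

#' Compute the seven bunch architecture traits
#'
#' From the accepted sphere models of one scan:
#' \describe{
#'   \item{n_berries}{number of accepted sphere models.}
#'   \item{mean_diameter}{mean of `2 * radius`, mm.}
#'   \item{mean_volume, total_volume}{mean and sum of the per-berry sphere
#'     volumes `(4/3) pi r^3`, reported in mL (1 mL = 1000 mm^3).}
#'   \item{convex_hull_volume}{volume of the 3D convex hull of the union of
#'     all models' inlier points, mL.}
#'   \item{length}{maximal vertical extent spanned by the detected berries,
#'     `max(cy + r) - min(cy - r)` -- the two vertically most distant
#'     berries, following the OIV 202 convention (y is the vertical axis).}
#'   \item{width}{the larger of the analogous extents along x and z.}
#' }
#'
#' @param models list of `sphere_model`s (after [resolve_overlaps()]).
#' @param cloud the working [point_cloud()] the inlier indices refer to.
#' @return A list of class `bunch_traits`.
#' @export
compute_traits <- function(models, cloud) {
  if (!length(models)) {
    return(structure(list(n_berries = 0L, mean_diameter = 0, mean_volume = 0,
                          total_volume = 0, convex_hull_volume = 0,
                          width = 0, length = 0),
                     class = "bunch_traits"))
  }
  stopifnot(inherits(cloud, "point_cloud"))
  radii <- vapply(models, function(m) m$radius, 1.0)
  centers <- t(vapply(models, function(m) m$center, numeric(3)))
  vol_mm3 <- 4 / 3 * pi * radii^3
  inlier_idx <- unique(unlist(lapply(models, function(m) m$inliers)))
  hull_mm3 <- if (length(inlier_idx) >= 4)
    convex_hull_volume(cloud$points[inlier_idx, , drop = FALSE])
  else {
    warning("fewer than 4 inlier points: hull volume set to 0")
    0
  }
  extent <- function(ax) {
    max(centers[, ax] + radii) - min(centers[, ax] - radii)
  }
  structure(list(
    n_berries = length(models),
    mean_diameter = mean(2 * radii),
    mean_volume = mean(vol_mm3) / 1000,
    total_volume = sum(vol_mm3) / 1000,
    convex_hull_volume = hull_mm3 / 1000,
    width = max(extent(1), extent(3)),
    length = extent(2)),
    class = "bunch_traits")
}

#' @export
print.bunch_traits <- function(x, ...) {
  cat("bunch_traits:\n")
  cat(sprintf("  berries:           %d\n", x$n_berries))
  cat(sprintf("  mean diameter:     %.2f mm\n", x$mean_diameter))
  cat(sprintf("  mean berry volume: %.4f mL\n", x$mean_volume))
  cat(sprintf("  total berry vol.:  %.2f mL\n", x$total_volume))
  cat(sprintf("  convex hull vol.:  %.2f mL\n", x$convex_hull_volume))
  cat(sprintf("  width:             %.1f mm\n", x$width))
  cat(sprintf("  length:            %.1f mm\n", x$length))
  invisible(x)
}

#' @export
as.data.frame.bunch_traits <- function(x, ...) {
  data.frame(n_berries = x$n_berries,
             mean_diameter_mm = x$mean_diameter,
             mean_volume_mL = x$mean_volume,
             total_volume_mL = x$total_volume,
             convex_hull_mL = x$convex_hull_volume,
             width_mm = x$width,
             length_mm = x$length)
}

#' Export bunch traits to a tab-separated text file
#'
#' One header line plus one data row, values rounded to 4 decimals at export
#' only (in-memory traits keep full precision). Re-exporting identical
#' traits yields a byte-identical file.
#'
#' @param traits a `bunch_traits` object.
#' @param path output `.txt` path.
#' @param scan_id identifier written in the first column.
#' @return Invisibly, `path`.
#' @export
export_traits <- function(traits, path, scan_id = "scan") {
  df <- cbind(scan_id = scan_id, round_traits_df(as.data.frame(traits)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

round_traits_df <- function(df) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) round(v, 4))
  df
}
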