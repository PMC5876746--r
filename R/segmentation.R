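#' Region-growing parameters
#'
#' Controls the segmentation of a cloud into smoothly connected regions.
#' Growth spreads over the k-nearest-neighbour graph; a neighbour joins a
#' region when the angle between its normal and the normal of the point that
#' recruited it is at most `angle_threshold`, and keeps propagating the front
#' only while its curvature stays at or below `curvature_threshold`. The
#' defaults keep a noiseless berry surface in one region while the
#' high-curvature creases between touching berries stop growth.
#'
#' @param k_neighbors neighbourhood size of the growth graph (>= 3).
#' @param angle_threshold smoothness threshold in degrees, in (0, 90).
#' @param curvature_threshold seed/propagation curvature gate in `[0, 1/3]`.
#' @param min_region_size regions smaller than this are reported as
#'   unassigned rather than passed to berry detection.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(k_neighbors = 30, angle_threshold = 15,
                                curvature_threshold = 0.05,
                                min_region_size = 50) {
  if (k_neighbors < 3) stop("k_neighbors must be >= 3")
  if (angle_threshold <= 0 || angle_threshold >= 90)
    stop("angle_threshold must be in (0, 90) degrees")
  if (curvature_threshold < 0 || curvature_threshold > 1 / 3)
    stop("curvature_threshold must be in [0, 1/3]")
  if (min_region_size < 1) stop("min_region_size must be >= 1")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 angle_threshold = angle_threshold,
                 curvature_threshold = curvature_threshold,
                 min_region_size = as.integer(min_region_size)),
            class = "segmentation_params")
}

#' Segment a cloud into smoothly connected regions
#'
#' Region growing over the kNN graph, seeds processed in ascending
#' (curvature, index) order so the partition is deterministic. Most regions
#' contain one berry; a region holding several berries (undersegmentation)
#' is tolerated because the detector fits spheres iteratively, and a berry
#' split over several regions (oversegmentation) is resolved later by
#' overlap suppression.
#'
#' @param cloud a [point_cloud()] carrying normals and curvature
#'   (see [estimate_normals()]).
#' @param params a [segmentation_params()] object.
#' @return A list of class `region_set` with elements `regions` (list of
#'   integer index vectors, each with a `seed` attribute), `unassigned`
#'   (indices in no region of size >= `min_region_size`) and `params`.
#' @export
region_growing <- function(cloud, params = segmentation_params()) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (is.null(cloud$normals) || is.null(cloud$curvature))
    stop("cloud must carry normals and curvature; run estimate_normals() first")
  n <- n_points(cloud)
  if (n == 0)
    return(structure(list(regions = list(), unassigned = integer(0),
                          params = params), class = "region_set"))
  k <- min(params$k_neighbors, n - 1L)
  nn <- cpp_knn(cloud$points, as.integer(k))
  res <- cpp_region_growing(cloud$normals, cloud$curvature, nn,
                            cos(params$angle_threshold * pi / 180),
                            params$curvature_threshold)
  labels <- res$label
  groups <- split(seq_len(n), labels)
  seeds <- res$seeds
  keep <- vapply(groups, length, 1L) >= params$min_region_size
  regions <- groups[keep]
  region_ids <- as.integer(names(regions))
  regions <- lapply(seq_along(regions), function(i) {
    r <- regions[[i]]
    attr(r, "seed") <- seeds[region_ids[i]]
    r
  })
  # larger regions first: berries before fragments, deterministic tie-break
  ord <- order(-vapply(regions, length, 1L),
               vapply(regions, function(r) r[1], 1L))
  regions <- regions[ord]
  unassigned <- sort(unlist(groups[!keep], use.names = FALSE))
  structure(list(regions = regions, unassigned = as.integer(unassigned),
                 params = params),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  sizes <- vapply(x$regions, length, 1L)
  cat(sprintf("region_set: %d regions (sizes %s), %d unassigned points\n",
              length(x$regions),
              if (length(sizes)) paste0(min(sizes), "..", max(sizes)) else "-",
              length(x$unassigned)))
  invisible(x)
}

#' Export a segmentation as a colored PLY for visual inspection
#'
#' Each region gets a deterministic color; unassigned points are grey.
#'
#' @param cloud the segmented [point_cloud()].
#' @param regions a `region_set` from [region_growing()].
#' @param path output PLY path.
#' @return Invisibly, `path`.
#' @export
export_regions_ply <- function(cloud, regions, path) {
  n <- n_points(cloud)
  colors <- matrix(128L, n, 3)
  palette <- cbind(
    r = as.integer((37 * seq_along(regions$regions) * 5) %% 200) + 55L,
    g = as.integer((91 * seq_along(regions$regions) * 7) %% 200) + 55L,
    b = as.integer((53 * seq_along(regions$regions) * 11) %% 200) + 55L)
  for (i in seq_along(regions$regions))
    colors[regions$regions[[i]], ] <- rep(palette[i, ], each =
                                            length(regions$regions[[i]]))
  write_ply(point_cloud(cloud$points, colors = colors), path)
}
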