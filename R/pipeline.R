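#' Run the full berry-detection workflow on one cloud
#'
#' The three-step workflow applied to a single scan: (1) voxel downsampling
#' to the working resolution, (2) normal estimation and region growing,
#' (3) iterative RANSAC sphere detection per region with overlap-based
#' suppression of duplicates, followed by trait extraction.
#'
#' @param cloud a [point_cloud()] (e.g. from [read_ply()]), mm coordinates,
#'   vertical axis y.
#' @param resolution working voxel resolution in mm (default 0.4).
#' @param seg a [segmentation_params()].
#' @param det a [detection_params()].
#' @param seed integer seed controlling the RANSAC streams; defaults to
#'   `det$random_seed`.
#' @return A list of class `bunch_analysis`: `traits` (the seven traits),
#'   `models` (accepted `sphere_model`s, inliers indexing `working`),
#'   `working` (the downsampled cloud with normals), `regions` (the
#'   `region_set`) and `log` (per-stage counts).
#' @export
analyze_bunch <- function(cloud, resolution = 0.4,
                          seg = segmentation_params(),
                          det = detection_params(),
                          seed = det$random_seed) {
  stopifnot(inherits(cloud, "point_cloud"))
  t0 <- proc.time()[["elapsed"]]
  working <- voxel_downsample(cloud, resolution)
  n_work <- n_points(working)
  if (n_work < seg$k_neighbors + 1) {
    return(structure(list(
      traits = compute_traits(list(), working), models = list(),
      working = working, regions = NULL,
      log = list(n_input = n_points(cloud), n_working = n_work,
                 n_regions = 0L, n_candidates = 0L, n_accepted = 0L,
                 elapsed = proc.time()[["elapsed"]] - t0)),
      class = "bunch_analysis"))
  }
  working <- estimate_normals(working, k = seg$k_neighbors)
  regions <- region_growing(working, seg)
  candidates <- list()
  for (i in seq_along(regions$regions)) {
    idx <- regions$regions[[i]]
    if (length(idx) < det$min_supporters) next
    region_seed <- (as.double(seed) + 1000003 * i) %% .Machine$integer.max
    models <- detect_berries_in_region(working$points[idx, , drop = FALSE],
                                       det, seed = as.integer(region_seed))
    for (m in models) {
      m$inliers <- idx[m$inliers]
      candidates[[length(candidates) + 1L]] <- m
    }
  }
  accepted <- resolve_overlaps(candidates, det$overlap_threshold)
  traits <- compute_traits(accepted, working)
  structure(list(traits = traits, models = accepted, working = working,
                 regions = regions,
                 log = list(n_input = n_points(cloud), n_working = n_work,
                            n_regions = length(regions$regions),
                            n_candidates = length(candidates),
                            n_accepted = length(accepted),
                            elapsed = proc.time()[["elapsed"]] - t0)),
            class = "bunch_analysis")
}

#' @export
print.bunch_analysis <- function(x, ...) {
  cat(sprintf("bunch_analysis: %d -> %d points, %d regions, %d candidate / %d accepted spheres\n",
              x$log$n_input, x$log$n_working, x$log$n_regions,
              x$log$n_candidates, x$log$n_accepted))
  print(x$traits)
  invisible(x)
}

# stable per-file seed so batch composition does not change single results
file_seed <- function(master_seed, file_name) {
  h <- 0
  for (code in utf8ToInt(basename(file_name)))
    h <- (h * 131 + code) %% 2147480009
  as.integer((as.double(master_seed) + h) %% 2147480009)
}

#' Batch processing of a folder of PLY scans
#'
#' Applies [analyze_bunch()] with one parameter set to every `.ply` file in
#' a folder (or to a single file), writes one tab-separated trait file per
#' scan, a combined CSV across scans, and a JSON run-metadata file capturing
#' all parameters and the seed. Files that fail to parse are logged and
#' skipped; the run fails only when no file could be processed.
#'
#' @param input a `.ply` file or a folder containing `.ply` files.
#' @param out_dir output folder (created if missing).
#' @param resolution working resolution, mm.
#' @param seg a [segmentation_params()].
#' @param det a [detection_params()].
#' @param seed master seed; each file derives its own stream from the seed
#'   and its file name, so batch order does not affect results.
#' @param factors optional named list of [factor_definition()]s; when given
#'   together with `ratings`, a per-factor Spearman report is written.
#' @param ratings optional data.frame (`scan_id`, `oiv204_class`) or CSV path.
#' @param verbose print one log line per scan.
#' @return Invisibly, the combined traits data.frame.
#' @export
run_pipeline <- function(input, out_dir, resolution = 0.4,
                         seg = segmentation_params(),
                         det = detection_params(),
                         seed = 1L, factors = NULL, ratings = NULL,
                         verbose = TRUE) {
  files <- if (dir.exists(input)) {
    sort(list.files(input, pattern = "\\.ply$", full.names = TRUE,
                    ignore.case = TRUE))
  } else if (file.exists(input)) input
  else stop(sprintf("input not found: %s", input))
  if (!length(files)) stop(sprintf("no PLY files found in %s", input))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  rows <- list()
  for (f in files) {
    scan_id <- sub("\\.ply$", "", basename(f), ignore.case = TRUE)
    res <- tryCatch({
      cloud <- read_ply(f)
      analyze_bunch(cloud, resolution = resolution, seg = seg, det = det,
                    seed = file_seed(seed, f))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("[skip] %s: %s", scan_id, conditionMessage(res)))
      next
    }
    if (verbose)
      message(sprintf(
        "[done] %s: %d -> %d pts, %d regions, %d candidates, %d berries (%.1f s)",
        scan_id, res$log$n_input, res$log$n_working, res$log$n_regions,
        res$log$n_candidates, res$log$n_accepted, res$log$elapsed))
    export_traits(res$traits, file.path(out_dir, paste0(scan_id, "_traits.txt")),
                  scan_id = scan_id)
    rows[[length(rows) + 1L]] <-
      cbind(scan_id = scan_id, round_traits_df(as.data.frame(res$traits)))
  }
  if (!length(rows)) stop("no PLY file could be processed")
  combined <- do.call(rbind, rows)
  write.table(combined, file.path(out_dir, "combined_traits.csv"), sep = ",",
              quote = FALSE, row.names = FALSE, eol = "\n")

  meta <- list(input = input, resolution = resolution,
               segmentation = unclass(seg), detection = unclass(det),
               seed = seed, n_files = length(files),
               n_processed = length(rows))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (!is.null(factors) && !is.null(ratings)) {
    if (is.character(ratings)) ratings <- read.table(ratings, sep = ",",
                                                     header = TRUE)
    rep <- compactness_report(combined, ratings, factors)
    write.table(rep, file.path(out_dir, "compactness_factors.csv"), sep = ",",
                quote = FALSE, row.names = FALSE, eol = "\n")
  }
  invisible(combined)
}
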