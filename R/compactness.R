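# Bunch compactness factors and their rank correlation with the visual
# OIV 204 descriptor (five classes: 1 very loose .. 9 very dense).

#' Define a compactness factor
#'
#' A factor is a named arithmetic expression over the fields of
#' [compute_traits()] output (`n_berries`, `mean_diameter`, `mean_volume`,
#' `total_volume`, `convex_hull_volume`, `width`, `length`).
#'
#' @param name factor label.
#' @param expression character arithmetic expression, e.g.
#'   `"total_volume / (length * width)"`.
#' @return A list of class `factor_definition`.
#' @export
factor_definition <- function(name, expression) {
  expr <- parse(text = expression)[[1]]
  vars <- all.vars(expr)
  fields <- c("n_berries", "mean_diameter", "mean_volume", "total_volume",
              "convex_hull_volume", "width", "length")
  bad <- setdiff(vars, fields)
  if (length(bad))
    stop(sprintf("factor '%s' references unknown trait field(s): %s",
                 name, paste(bad, collapse = ", ")))
  structure(list(name = name, expression = expression, expr = expr),
            class = "factor_definition")
}

#' Default compactness factor registry
#'
#' Candidate factors relating berry volume and bunch extent. These are the
#' package's own working interpretations of volume/extent compactness
#' ratios, not verbatim published formulas; replace or extend them via
#' [factor_definition()] or a plain-text config (see
#' [read_factor_config()]). Factor A (a published external index) is not
#' shipped and must be user supplied.
#'
#' @return Named list of `factor_definition`s.
#' @export
default_factors <- function() {
  list(
    B = factor_definition("B", "total_volume * 1000 / (length * width)"),
    C = factor_definition("C", "total_volume * 1000 / length"),
    D = factor_definition("D", "total_volume / convex_hull_volume"),
    E = factor_definition("E", "convex_hull_volume * 1000 / (length * width)"))
}

#' Evaluate a compactness factor on one trait record
#'
#' @param definition a [factor_definition()].
#' @param traits a `bunch_traits` object (or a list/one-row data frame with
#'   the same field names).
#' @return The factor value (finite number).
#' @export
evaluate_factor <- function(definition, traits) {
  stopifnot(inherits(definition, "factor_definition"))
  env <- as.list(traits)
  val <- eval(definition$expr, envir = env)
  if (!is.finite(val))
    stop(sprintf("factor '%s' evaluates to a non-finite value (zero denominator?)",
                 definition$name))
  as.numeric(val)
}

#' Read factor definitions from a plain-text config
#'
#' One factor per line, `name = expression`; blank lines and `#` comments
#' are skipped.
#'
#' @param path config file path.
#' @return Named list of `factor_definition`s.
#' @export
read_factor_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("factor config not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  defs <- lapply(lines, function(l) {
    eq <- regexpr("=", l, fixed = TRUE)
    if (eq < 0) stop(sprintf("bad factor config line (no '='): %s", l))
    factor_definition(trimws(substr(l, 1, eq - 1)),
                      trimws(substr(l, eq + 1, nchar(l))))
  })
  setNames(defs, vapply(defs, `[[`, "", "name"))
}

#' Spearman rank correlation with average-rank ties
#'
#' Rank correlation between factor values and ordinal class labels. Ties are
#' pervasive on OIV 204 data (five class levels), so average ranks are used
#' on both sides; the result is invariant under strictly monotone transforms
#' of either vector.
#'
#' @param values numeric vector of factor values.
#' @param classes numeric/integer vector of class labels, same length.
#' @return Spearman's rho in `[-1, 1]`.
#' @export
spearman_rank_correlation <- function(values, classes) {
  if (length(values) != length(classes))
    stop("values and classes must have equal length")
  if (length(values) < 3) stop("need at least 3 observations")
  if (anyNA(values) || anyNA(classes)) stop("missing values not allowed")
  if (diff(range(values)) == 0 || diff(range(classes)) == 0)
    stop("correlation undefined for a constant vector")
  cor(rank(values, ties.method = "average"),
      rank(classes, ties.method = "average"), method = "pearson")
}

#' Per-factor rank correlation report
#'
#' Joins a trait table with OIV 204 ratings by `scan_id` and reports
#' Spearman's rho of every factor against the class labels.
#'
#' @param traits_df data frame with a `scan_id` column plus the trait
#'   columns produced by [export_traits()] (`*_mm`, `*_mL` names) or raw
#'   trait field names.
#' @param ratings data frame with columns `scan_id` and `oiv204_class`
#'   (classes in 1, 3, 5, 7, 9).
#' @param factors named list of [factor_definition()]s.
#' @return data.frame with columns `factor`, `rho`, `n`.
#' @export
compactness_report <- function(traits_df, ratings,
                               factors = default_factors()) {
  if (!all(c("scan_id", "oiv204_class") %in% names(ratings)))
    stop("ratings must have columns scan_id and oiv204_class")
  if (!all(ratings$oiv204_class %in% c(1, 3, 5, 7, 9)))
    stop("oiv204_class values must be in {1, 3, 5, 7, 9}")
  # accept exported column names as well as in-memory field names
  ren <- c(mean_diameter_mm = "mean_diameter", mean_volume_mL = "mean_volume",
           total_volume_mL = "total_volume", convex_hull_mL = "convex_hull_volume",
           width_mm = "width", length_mm = "length")
  for (from in names(ren))
    if (from %in% names(traits_df) && !ren[[from]] %in% names(traits_df))
      names(traits_df)[names(traits_df) == from] <- ren[[from]]
  merged <- merge(traits_df, ratings, by = "scan_id")
  if (nrow(merged) < 3) stop("fewer than 3 scans with both traits and ratings")
  rows <- lapply(factors, function(f) {
    vals <- vapply(seq_len(nrow(merged)),
                   function(i) evaluate_factor(f, merged[i, ]), 1.0)
    data.frame(factor = f$name,
               rho = spearman_rank_correlation(vals, merged$oiv204_class),
               n = nrow(merged))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
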