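#' Classify months into hypoxia and normoxia seasons
#'
#' A month is labelled `hypoxia` when the minimum dissolved-oxygen
#' concentration over all that month's samples (both layers) falls strictly
#' below the threshold, 2 mg/L by default -- the conventional hypoxia
#' threshold in the coastal-ecology literature.  All samples of a hypoxic
#' month share the label, so that samples collected in the same period are
#' analysed as one unit.
#'
#' @param env Environmental data frame as from [read_env_table()].
#' @param metadata Sample metadata (supplies the month of each sample).
#' @param threshold Hypoxia threshold in mg/L (> 0); strict `<` comparison.
#' @return An object of class `season_labeling`: a data frame with one row
#'   per month (`month`, `min_do`, `season`), `threshold` stored as an
#'   attribute.
#' @export
classify_seasons <- function(env, metadata, threshold = 2) {
  stopifnot(threshold > 0)
  months <- sort(unique(metadata$month))
  do_by_month <- split(env$dissolved_oxygen[match(metadata$sample_id, env$sample_id)],
                       metadata$month)
  empty <- months[vapply(do_by_month[as.character(months)],
                         function(v) all(is.na(v)) || length(v) == 0, logical(1))]
  if (length(empty)) {
    stop("no dissolved-oxygen values for month(s): ", paste(empty, collapse = ", "))
  }
  min_do <- vapply(do_by_month[as.character(months)],
                   function(v) min(v, na.rm = TRUE), numeric(1))
  out <- data.frame(month = months,
                    min_do = unname(min_do),
                    season = ifelse(min_do < threshold, "hypoxia", "normoxia"),
                    stringsAsFactors = FALSE)
  structure(out, class = c("season_labeling", "data.frame"), threshold = threshold)
}

#' Season label for given months
#'
#' @param labeling A `season_labeling`.
#' @param month Integer vector of months.
#' @return Factor with levels `hypoxia`, `normoxia`.
#' @export
season_of <- function(labeling, month) {
  i <- match(month, labeling$month)
  if (anyNA(i)) stop("month(s) without a season label: ",
                     paste(unique(month[is.na(i)]), collapse = ", "))
  factor(labeling$season[i], levels = c("hypoxia", "normoxia"))
}

#' Principal components analysis of environmental variables
#'
#' Centred (and by default unit-variance scaled) PCA via eigendecomposition
#' of the covariance/correlation matrix.  Scaling is the default because
#' dissolved oxygen, temperature, and salinity carry incommensurable units.
#' For reproducible plots each component's sign is fixed so its
#' largest-magnitude loading is positive.
#'
#' @param x Numeric matrix or data frame, samples in rows.
#' @param standardize Scale variables to unit variance (default `TRUE`).
#' @return An object of class `env_pca`: list with `scores`
#'   (samples x components), `loadings` (variables x components), and
#'   `variance_fraction` (per-component fractions summing to 1).
#' @export
run_pca <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("PCA input contains missing values")
  if (nrow(x) <= ncol(x)) stop("PCA needs more samples than variables")
  sds <- apply(x, 2, sd)
  if (standardize && any(sds == 0)) {
    stop("constant variable(s) cannot be standardized: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  p <- prcomp(x, center = TRUE, scale. = standardize)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    l <- p$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(p$x, 2, flip, "*")
  loadings <- sweep(p$rotation, 2, flip, "*")
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = p$sdev^2 / sum(p$sdev^2)),
            class = "env_pca")
}

#' @export
print.env_pca <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples,", ncol(x$loadings), "components\n")
  cat("variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "), "\n")
  invisible(x)
}
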