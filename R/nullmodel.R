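#' Configuration for the fixed-fixed swap null model
#'
#' Defaults follow the analysis design: 999 null matrices per month, a
#' burn-in of `10 * fill` trial swaps and `1 * fill` trial swaps between
#' consecutive draws of a single sequential chain (`fill` = number of
#' occurrences in the month's matrix), months with fewer than 3 samples
#' skipped, and a 10-90% null band.
#'
#' @param n_null Number of null matrices per month (>= 1).
#' @param burn_in_swaps Trial swaps before the first draw; `NULL` =
#'   `10 * fill`.
#' @param swaps_between_draws Trial swaps between draws; `NULL` = `fill`.
#' @param seed Integer seed for the swap chains.
#' @param min_samples_per_month Months with fewer samples are skipped.
#' @param quantile_bounds Lower/upper quantiles of the null band.
#' @return A list of class `null_model_config`.
#' @export
null_model_config <- function(n_null = 999, burn_in_swaps = NULL,
                              swaps_between_draws = NULL, seed = NULL,
                              min_samples_per_month = 3,
                              quantile_bounds = c(0.10, 0.90)) {
  stopifnot(n_null >= 1, length(quantile_bounds) == 2,
            quantile_bounds[1] < quantile_bounds[2],
            all(quantile_bounds >= 0), all(quantile_bounds <= 1))
  structure(list(n_null = as.integer(n_null),
                 burn_in_swaps = burn_in_swaps,
                 swaps_between_draws = swaps_between_draws,
                 seed = seed,
                 min_samples_per_month = as.integer(min_samples_per_month),
                 quantile_bounds = quantile_bounds),
            class = "null_model_config")
}

#' Fixed-fixed randomization of a binary matrix by trial swaps
#'
#' Performs `n_swaps` trial swaps: two random rows and two random columns are
#' picked, and if their 2x2 submatrix is a checkerboard it is flipped.  Row
#' sums (sample richness) and column sums (species occurrence totals) are
#' preserved exactly; matrices with no checkerboard submatrix pass through
#' unchanged.
#'
#' @param m Binary matrix (or `community_matrix`).
#' @param n_swaps Number of trial swaps.
#' @return Randomized integer matrix with the dimnames of the input.
#' @export
swap_randomize <- function(m, n_swaps) {
  occ <- occupancy_of(m)
  storage.mode(occ) <- "integer"
  swap_randomize_cpp(occ, as.integer(n_swaps))
}

#' Per-pair null quantiles of Jaccard dissimilarity
#'
#' For every month with enough samples, runs one sequential fixed-fixed swap
#' chain on that month's community submatrix (shared regional species pool),
#' draws `n_null` randomized matrices, and records, for every unordered
#' same-month sample pair, the observed Jaccard dissimilarity and its
#' mid-rank quantile position in the null distribution:
#' `q = (#\{null < obs\} + 0.5 #\{null = obs\}) / n_null`.  Low quantiles mean
#' the pair is more similar than expected after fixing sample richness and
#' species totals; the mid-rank definition handles the heavy ties of Jaccard
#' values on small binary matrices.
#'
#' Pairs sharing a sample are not independent; the comparison downstream
#' deliberately retains this structure (see the package vignette).
#'
#' @param cm A `community_matrix`.
#' @param labeling A `season_labeling` (used to attach season labels).
#' @param config A [null_model_config()].
#' @return Data frame of class `pair_null_quantiles`: one row per pair with
#'   `month`, `season`, `sample_a`, `sample_b`, `observed`, `quantile`,
#'   `ses` (standardized effect size, `(obs - mean(null)) / sd(null)`,
#'   provided as a convenience), and `within_bounds`.  Skipped months are
#'   recorded in attribute `skipped_months`.
#' @export
pairwise_null_quantiles <- function(cm, labeling, config = null_model_config()) {
  stopifnot(inherits(cm, "community_matrix"),
            inherits(config, "null_model_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  months <- sort(unique(cm$samples$month))
  res <- list()
  skipped <- integer()
  for (mo in months) {
    rows <- which(cm$samples$month == mo)
    if (length(rows) < config$min_samples_per_month) {
      message("month ", mo, ": only ", length(rows),
              " sample(s); skipped from the null model")
      skipped <- c(skipped, mo)
      next
    }
    sub <- cm$occupancy[rows, , drop = FALSE]
    storage.mode(sub) <- "integer"
    fill <- sum(sub)
    burn <- if (is.null(config$burn_in_swaps)) 10L * fill else as.integer(config$burn_in_swaps)
    thin <- if (is.null(config$swaps_between_draws)) fill else as.integer(config$swaps_between_draws)
    pr <- t(combn(length(rows), 2L))
    # observed Jaccard with the same arithmetic as the null kernel, so that
    # ties between observed and null values are detected exactly
    inter <- tcrossprod(sub)
    rich <- rowSums(sub)
    uni <- outer(rich, rich, "+") - inter
    obs <- ifelse(uni[pr] == 0, 0, 1 - inter[pr] / uni[pr])
    nulls <- null_pair_jaccard_cpp(sub, pr - 1L, config$n_null, burn, thin, TRUE)
    qb <- config$quantile_bounds
    quant <- numeric(nrow(pr))
    within <- logical(nrow(pr))
    ses <- numeric(nrow(pr))
    for (p in seq_len(nrow(pr))) {
      nv <- nulls[p, ]
      quant[p] <- (sum(nv < obs[p]) + 0.5 * sum(nv == obs[p])) / config$n_null
      band <- quantile(nv, qb, names = FALSE)
      within[p] <- obs[p] >= band[1] && obs[p] <= band[2]
      s <- sd(nv)
      ses[p] <- if (s > 0) (obs[p] - mean(nv)) / s else 0
    }
    ids <- rownames(sub)
    res[[as.character(mo)]] <- data.frame(
      month = mo,
      sample_a = ids[pr[, 1]],
      sample_b = ids[pr[, 2]],
      observed = obs,
      quantile = quant,
      ses = ses,
      within_bounds = within,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$season <- as.character(season_of(labeling, out$month))
  out <- out[, c("month", "season", "sample_a", "sample_b",
                 "observed", "quantile", "ses", "within_bounds")]
  structure(out, class = c("pair_null_quantiles", "data.frame"),
            skipped_months = skipped, config = config)
}

#' Compare null quantiles between hypoxia and normoxia pairs
#'
#' Two-sided Wilcoxon rank-sum test on the per-pair null quantiles of the
#' two seasons (mid-rank ties; exact enumeration when both groups have at
#' most 12 values and no ties, tie-corrected normal approximation
#' otherwise).
#'
#' @param pairs A `pair_null_quantiles` data frame (or any data frame with
#'   `season` and `quantile` columns).
#' @param labeling Ignored if `pairs` already carries a `season` column;
#'   otherwise used to label months.
#' @return List of class `season_comparison` with `quantiles_hypoxia`,
#'   `quantiles_normoxia`, `rank_sum_statistic`, `p_value`, `exact`.
#' @export
compare_quantiles_by_season <- function(pairs, labeling = NULL) {
  if (!("season" %in% names(pairs))) {
    if (is.null(labeling)) stop("need a season_labeling when pairs lack a season column")
    pairs$season <- as.character(season_of(labeling, pairs$month))
  }
  qh <- pairs$quantile[pairs$season == "hypoxia"]
  qn <- pairs$quantile[pairs$season == "normoxia"]
  if (length(qh) == 0 || length(qn) == 0) {
    stop("both seasons need at least one sample pair")
  }
  ties <- anyDuplicated(c(qh, qn)) > 0
  exact <- length(qh) <= 12 && length(qn) <= 12 && !ties
  wt <- suppressWarnings(
    wilcox.test(qh, qn, alternative = "two.sided", exact = exact,
                correct = !exact))
  structure(list(quantiles_hypoxia = qh,
                 quantiles_normoxia = qn,
                 rank_sum_statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 exact = exact),
            class = "season_comparison")
}

#' @export
print.season_comparison <- function(x, ...) {
  cat(sprintf(
    "null-quantile comparison: hypoxia n=%d (mean %.3f), normoxia n=%d (mean %.3f)\n",
    length(x$quantiles_hypoxia), mean(x$quantiles_hypoxia),
    length(x$quantiles_normoxia), mean(x$quantiles_normoxia)))
  cat(sprintf("Wilcoxon rank-sum W = %.1f, p = %.4g (%s)\n",
              x$rank_sum_statistic, x$p_value,
              if (x$exact) "exact" else "normal approximation"))
  invisible(x)
}
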