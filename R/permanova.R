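#' Permutational multivariate analysis of variance on a distance matrix
#'
#' Partitions the total sum of squares of a distance matrix among an ordered
#' list of model terms (factors, continuous covariates, and interactions),
#' following the distance-based partitioning of Gower-centred squared
#' distances.  Writing `A = -D^2/2` and `G = C A C` with
#' `C = I - 11'/n` the centering operator, the sequential (Type I) sum of
#' squares of term j is `tr((H_j - H_{j-1}) G)`, where `H_j` is the
#' orthogonal projection onto the model matrix of the first j terms, and the
#' residual SS is `tr((I - H_full) G)`.  Pseudo-F uses the residual from the
#' full model; significance comes from free permutation of sample labels
#' (rows and columns of `G` permuted together).
#'
#' Continuous covariates are centred before interactions are formed, which
#' decorrelates main-effect and interaction columns.
#'
#' @param d A [stats::dist] of pairwise dissimilarities.
#' @param data Data frame of per-sample predictors, rows aligned with `d`.
#' @param terms Character vector of model terms in testing order, e.g.
#'   `c("season", "layer", "season:layer")`.
#' @param n_perm Number of permutations (>= 1; default 999).
#' @param seed Integer seed for the permutation stream (required for
#'   reproducibility).
#' @return Object of class `permanova`: list with `aov_table` (one row per
#'   term plus Residual and Total: Df, SumOfSqs, R2, F, p), `n_perm`,
#'   `terms`.
#' @export
permanova <- function(d, data, terms, n_perm = 999, seed) {
  stopifnot(inherits(d, "dist"), is.data.frame(data), n_perm >= 1)
  n <- attr(d, "Size")
  if (nrow(data) != n) stop("data rows must align with the distance matrix")
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(seed)

  # centre continuous covariates so interactions are decorrelated from mains
  num_vars <- names(data)[vapply(data, is.numeric, logical(1))]
  for (v in num_vars) data[[v]] <- data[[v]] - mean(data[[v]])

  G <- gower_center(as.matrix(d))
  X <- stats::model.matrix(stats::reformulate(terms), data = data)
  asg <- attr(X, "assign")
  k <- length(terms)

  # cumulative projections H_0 (intercept) .. H_k (full model)
  H_prev <- matrix(1 / n, n, n)
  rank_prev <- 1L
  P <- vector("list", k)
  df <- integer(k)
  for (j in seq_len(k)) {
    Xj <- X[, asg <= j, drop = FALSE]
    qrj <- qr(Xj)
    rank_j <- qrj$rank
    if (j == k && rank_j < ncol(Xj)) {
      aliased <- unique(asg[setdiff(seq_len(ncol(Xj)), qrj$pivot[seq_len(rank_j)])])
      aliased <- aliased[aliased > 0]
      stop("rank-deficient model; aliased term(s): ",
           paste(terms[aliased], collapse = ", "))
    }
    Q <- qr.Q(qrj)[, seq_len(rank_j), drop = FALSE]
    Hj <- tcrossprod(Q)
    P[[j]] <- Hj - H_prev
    df[j] <- rank_j - rank_prev
    H_prev <- Hj
    rank_prev <- rank_j
  }
  if (any(df == 0L)) {
    stop("rank-deficient model; aliased term(s): ",
         paste(terms[df == 0L], collapse = ", "))
  }
  R <- diag(n) - H_prev
  df_res <- n - rank_prev

  ss <- vapply(P, function(p) sum(p * G), numeric(1))
  ss_res <- sum(R * G)
  ss_total <- sum(diag(G))
  f_obs <- (ss / df) / (ss_res / df_res)

  exceed <- numeric(k)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    Gp <- G[idx, idx]
    ssr_p <- sum(R * Gp)
    fp <- vapply(seq_len(k), function(j) {
      (sum(P[[j]] * Gp) / df[j]) / (ssr_p / df_res)
    }, numeric(1))
    exceed <- exceed + (fp >= f_obs)
  }
  pval <- (1 + exceed) / (1 + n_perm)

  tab <- data.frame(
    term = c(terms, "Residual", "Total"),
    Df = c(df, df_res, n - 1L),
    SumOfSqs = c(ss, ss_res, ss_total),
    R2 = c(ss / ss_total, ss_res / ss_total, 1),
    F = c(f_obs, NA, NA),
    p = c(pval, NA, NA),
    stringsAsFactors = FALSE
  )
  structure(list(aov_table = tab, n_perm = n_perm, terms = terms),
            class = "permanova")
}

gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  rm <- rowMeans(A)
  A - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(A)
}

#' @export
print.permanova <- function(x, digits = 4, ...) {
  cat("PERMANOVA (sequential SS,", x$n_perm, "free permutations)\n")
  tab <- x$aov_table
  tab$SumOfSqs <- signif(tab$SumOfSqs, digits)
  tab$R2 <- signif(tab$R2, digits)
  tab$F <- signif(tab$F, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
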