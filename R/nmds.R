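#' Nonmetric multidimensional scaling with multiple restarts
#'
#' Minimizes Kruskal stress-1,
#' `sqrt(sum((dhat_ij - dstar_ij)^2) / sum(dhat_ij^2))`, where `dstar` are
#' configuration distances monotonically (isotonically) regressed on the
#' input dissimilarities (primary/weak tie treatment, so stress depends only
#' on the rank order of the dissimilarities).  The first start is the metric
#' (classical scaling) configuration; remaining restarts jitter it with
#' Gaussian noise, and the lowest-stress solution is returned.  The gradient
#' engine is [vegan::monoMDS].
#'
#' @param d A [stats::dist] of dissimilarities.
#' @param k Number of dimensions (>= 1).
#' @param n_restarts Number of starting configurations (>= 1; default 20).
#' @param max_iter Maximum gradient iterations per start.
#' @param tol Relative stress-change convergence tolerance.
#' @param seed Optional integer seed for the restart jitter.
#' @return Object of class `nmds_ordination`: list with `coordinates`
#'   (samples x k, centred), `stress`, `k`, `converged`, `n_restarts`, and
#'   `restart_stress` (final stress of every start).
#' @export
nmds <- function(d, k = 3, n_restarts = 20, max_iter = 500, tol = 1e-6,
                 seed = NULL) {
  stopifnot(inherits(d, "dist"), k >= 1, n_restarts >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- attr(d, "Size")
  init <- cmdscale(d, k = k)
  if (ncol(init) < k) {  # degenerate double-centred matrix: pad
    init <- cbind(init, matrix(0, n, k - ncol(init)))
  }
  jitter_sd <- max(stats::sd(init), 1e-3) / 10
  best <- NULL
  restart_stress <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    y0 <- if (r == 1L) init else init + matrix(rnorm(n * k, sd = jitter_sd), n, k)
    fit <- vegan::monoMDS(d, y = y0, k = k, model = "global",
                          maxit = max_iter, sratmax = 1 - tol,
                          weakties = TRUE)
    restart_stress[r] <- fit$stress
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  coords <- scale(best$points, center = TRUE, scale = FALSE)
  dimnames(coords) <- list(attr(d, "Labels"), paste0("MDS", seq_len(k)))
  structure(list(coordinates = coords,
                 stress = best$stress,
                 k = k,
                 converged = best$icause != 1L,
                 n_restarts = n_restarts,
                 restart_stress = restart_stress),
            class = "nmds_ordination")
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat(sprintf("NMDS: %d points, k = %d, stress = %.4f (%s, best of %d starts)\n",
              nrow(x$coordinates), x$k, x$stress,
              if (x$converged) "converged" else "not converged", x$n_restarts))
  invisible(x)
}

#' Distance between group centroids in ordination space
#'
#' Euclidean distance between the per-group means of the ordination
#' coordinates over the first `dims` dimensions.
#'
#' @param ordination An `nmds_ordination` (or any matrix-like coordinates).
#' @param groups Vector of group labels, one per sample (ordination row).
#' @param group_a,group_b The two groups to compare.
#' @param dims Number of leading dimensions to use (default: all).
#' @return Non-negative scalar distance.
#' @export
centroid_distance <- function(ordination, groups, group_a, group_b, dims = NULL) {
  coords <- if (inherits(ordination, "nmds_ordination")) {
    ordination$coordinates
  } else {
    as.matrix(ordination)
  }
  if (is.null(dims)) dims <- ncol(coords)
  stopifnot(length(groups) == nrow(coords), dims >= 1, dims <= ncol(coords))
  a <- coords[groups == group_a, seq_len(dims), drop = FALSE]
  b <- coords[groups == group_b, seq_len(dims), drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty group in centroid_distance")
  sqrt(sum((colMeans(a) - colMeans(b))^2))
}
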