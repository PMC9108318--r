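#' Fit a hierarchical generalized linear mixed model
#'
#' Thin wrapper around [glmmTMB::glmmTMB] (Laplace-approximated marginal
#' likelihood) returning a compact fit object.  Random effects written with
#' `diag(...)` have independent (diagonal) covariance, the package default
#' for the occurrence model; ordinary `(...|g)` terms are fully correlated.
#'
#' @param formula Model formula, e.g.
#'   `y ~ season * layer + diag(1 + season + layer | species)`.
#' @param data Data frame of complete cases.
#' @param family `"poisson"` (log link) or `"binomial"` (logit link).
#' @return Object of class `glmm_fit`: list with `fixed` (term, estimate,
#'   se, z, p -- two-sided Wald, normal reference), `random` (group, term,
#'   variance), `log_likelihood`, `n_parameters`, `converged`, `n_obs`,
#'   `family`, and the underlying `model`.
#' @export
fit_glmm <- function(formula, data, family = c("poisson", "binomial")) {
  family <- match.arg(family)
  if (anyNA(data)) stop("data must be complete cases")
  for (g in grouping_vars(formula)) {
    if (length(unique(data[[g]])) < 2L) {
      stop("grouping variable '", g, "' has fewer than 2 levels")
    }
  }
  fam <- if (family == "poisson") stats::poisson(link = "log") else
    stats::binomial(link = "logit")
  fit <- glmmTMB::glmmTMB(formula, data = data, family = fam)
  sm <- summary(fit)
  co <- sm$coefficients$cond
  fixed <- data.frame(term = rownames(co),
                      estimate = co[, "Estimate"],
                      se = co[, "Std. Error"],
                      z = co[, "z value"],
                      p = co[, "Pr(>|z|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  vc <- glmmTMB::VarCorr(fit)$cond
  random <- if (length(vc)) {
    do.call(rbind, lapply(names(vc), function(g) {
      v <- diag(as.matrix(vc[[g]]))
      data.frame(group = g, term = names(v), variance = unname(v),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(group = character(), term = character(), variance = numeric())
  }
  ll <- logLik(fit)
  conv <- isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
  structure(list(fixed = fixed, random = random,
                 log_likelihood = as.numeric(ll),
                 n_parameters = attr(ll, "df"),
                 converged = conv,
                 n_obs = stats::nobs(fit),
                 family = family,
                 formula = formula,
                 model = fit),
            class = "glmm_fit")
}

grouping_vars <- function(formula) {
  txt <- paste(deparse(formula), collapse = " ")
  m <- regmatches(txt, gregexpr("\\|\\|?[^)]*\\)", txt))[[1]]
  unique(trimws(sub("^\\|\\|?", "", sub("\\)$", "", m))))
}

#' @export
print.glmm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("GLMM (%s, Laplace): n = %d, logLik = %.2f, %s\n",
              x$family, x$n_obs, x$log_likelihood,
              if (x$converged) "converged" else "NOT converged"))
  fx <- x$fixed
  fx[-1] <- lapply(fx[-1], signif, digits)
  print(fx, row.names = FALSE)
  if (nrow(x$random)) {
    cat("random-effect variances:\n")
    rd <- x$random
    rd$variance <- signif(rd$variance, digits)
    print(rd, row.names = FALSE)
  }
  invisible(x)
}

#' Poisson richness model with site random intercept
#'
#' Models per-sample species richness as a function of season, water layer,
#' and their interaction (log link), with a site-level random intercept.
#' Season is dummy-coded with normoxia as the reference (hypoxia = 1) and
#' layer with surface as the reference (bottom = 1).
#'
#' @param cm A `community_matrix`.
#' @param labeling A `season_labeling`.
#' @return A `glmm_fit`.
#' @export
fit_richness_glmm <- function(cm, labeling) {
  d <- data.frame(richness = compute_richness(cm),
                  hypoxia = as.integer(season_of(labeling, cm$samples$month) == "hypoxia"),
                  bottom = as.integer(cm$samples$layer == "bottom"),
                  site = factor(cm$samples$site_id))
  fit_glmm(richness ~ hypoxia * bottom + (1 | site), d, family = "poisson")
}

#' Long-format occurrence data for the hierarchical occurrence model
#'
#' One row per (species, sample) with the model's fixed dummy coding:
#' season (hypoxia = 0, normoxia = 1) and layer (surface = 0, bottom = 1).
#'
#' @param cm A `community_matrix`.
#' @param labeling A `season_labeling`.
#' @param species Species subset (default: all columns of `cm`).
#' @return Data frame with `presence`, `season`, `layer`, `species`,
#'   `sample_id`, `site`.
#' @export
occurrence_data <- function(cm, labeling, species = NULL) {
  if (is.null(species)) species <- colnames(cm$occupancy)
  missing_sp <- setdiff(species, colnames(cm$occupancy))
  if (length(missing_sp)) stop("unknown species: ", paste(missing_sp, collapse = ", "))
  occ <- cm$occupancy[, species, drop = FALSE]
  n <- nrow(occ)
  data.frame(
    presence = as.integer(occ),
    season = rep(as.integer(season_of(labeling, cm$samples$month) == "normoxia"),
                 times = length(species)),
    layer = rep(as.integer(cm$samples$layer == "bottom"), times = length(species)),
    species = factor(rep(species, each = n), levels = species),
    sample_id = rep(cm$samples$sample_id, times = length(species)),
    site = rep(cm$samples$site_id, times = length(species)),
    stringsAsFactors = FALSE)
}

#' Hierarchical occurrence model (Bernoulli-logit, species random effects)
#'
#' Fits `logit(p) = b0_i + b1_i * season + b2_i * layer +
#' b3_i * season * layer`, where each species-level coefficient is a fixed
#' effect plus an independent normal deviation.  With
#' `random_interaction = FALSE` the interaction is a purely fixed effect
#' (the reduced model of the likelihood-ratio comparison).
#'
#' @param cm A `community_matrix`.
#' @param labeling A `season_labeling`.
#' @param species Species subset; default the top 10% most frequent species.
#' @param random_interaction Give the interaction a species-specific random
#'   deviation (default `TRUE`).
#' @return A `glmm_fit`.
#' @export
fit_occurrence_glmm <- function(cm, labeling, species = NULL,
                                random_interaction = TRUE) {
  if (is.null(species)) species <- select_top_species(cm, 0.10)
  d <- occurrence_data(cm, labeling, species)
  f <- if (random_interaction) {
    presence ~ season * layer + diag(1 + season + layer + season:layer | species)
  } else {
    presence ~ season * layer + diag(1 + season + layer | species)
  }
  fit_glmm(f, d, family = "binomial")
}

#' Likelihood-ratio test between nested GLMM fits
#'
#' `chi2 = 2 (logLik_full - logLik_reduced)` clipped at zero; degrees of
#' freedom are the difference in parameter counts; p-value from the
#' chi-square upper tail.  Testing a variance component places the null on
#' the parameter-space boundary; as is conventional in the reporting style
#' this mirrors, no boundary correction is applied.
#'
#' @param fit_full,fit_reduced `glmm_fit` objects, reduced nested in full.
#' @param tol Tolerance for a negative log-likelihood difference before a
#'   convergence warning is raised.
#' @return List with `chi2`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(fit_full, fit_reduced, tol = 1e-6) {
  chi2 <- 2 * (fit_full$log_likelihood - fit_reduced$log_likelihood)
  if (chi2 < -tol) {
    warning("full model has lower log-likelihood than reduced model; ",
            "optimizer failure suspected")
  }
  chi2 <- max(0, chi2)
  df <- fit_full$n_parameters - fit_reduced$n_parameters
  p <- if (df == 0L) {
    if (chi2 <= tol) 1 else 0
  } else {
    pchisq(chi2, df = df, lower.tail = FALSE)
  }
  list(chi2 = chi2, df = df, p_value = p)
}
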