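#' Configuration for the synthetic metacommunity generator
#'
#' The defaults emulate the study design the package is built around: 14
#' sites sampled monthly for 12 months at two layers (surface and bottom,
#' about 336 samples), a pool of 170 species, and a summer (June-September)
#' bottom dissolved-oxygen collapse below 2 mg/L.  Species occupancy follows
#' the hierarchical logistic occurrence model: per-species coefficients for
#' season (hypoxia = 0, normoxia = 1), layer (surface = 0, bottom = 1), and
#' their interaction are drawn from normal distributions whose means mirror
#' the magnitudes estimated for common coastal fish species (baseline
#' occupancy driven by a wide intercept spread; layer effect ~ +0.5 logits
#' for bottom in normoxia; season effect ~ -0.4; interaction ~ +0.6, i.e.
#' bottom occupancy depressed during hypoxia).
#'
#' Beyond the layer/season effects, each species carries persistent
#' site-specific affinity logits (`~ N(0, site_affinity_sd)`, independent
#' across species and sites), representing patchy, localized distributions
#' across the bay's heterogeneous habitats -- horizontal species sorting
#' strong enough that many species are effectively restricted to a subset
#' of sites.  Assembly
#' scenarios differ in the interaction spread across species and in how much
#' of the species-specific spatial structure survives the hypoxic months:
#' * `neutral_avoidance` -- near-zero interaction SD: all species shift
#'   surface-ward during hypoxia to the same degree (an occupancy shift,
#'   not mortality), and mass-effect-like dispersal mixes individuals
#'   across sites during hypoxia: a fraction `hypoxia_mixing` of each
#'   species' occupancy probability is replaced by its bay-wide
#'   (site-averaged) value, eroding spatial structure irrespective of
#'   species identity while preserving every species' overall occupancy.
#' * `sorting` -- large interaction SD with mixed-sign species effects:
#'   species-specific responses to bottom hypoxia (species sorting); site
#'   structure is expressed equally in both seasons.
#' * `null` -- all layer/season/interaction effects zero: no assembly
#'   structure beyond baseline occupancy and site affinity.
#'
#' @param n_sites Number of sampling sites.
#' @param months Months sampled (subset of 1-12).
#' @param site_depths Site depths in metres; default evenly spaced 6-70 m.
#' @param species_pool Species pool size.
#' @param scenario Assembly scenario (see above).
#' @param intercept_mean,intercept_sd Baseline occupancy logit distribution.
#' @param layer_mean,layer_sd Layer (bottom) effect distribution.
#' @param season_mean,season_sd Season (normoxia) effect distribution.
#' @param interaction_mean Interaction (normoxia x bottom) mean; `NULL` =
#'   scenario default (1.5 for `neutral_avoidance` -- the conditional
#'   avoidance effect is set above the marginal fitted magnitude because
#'   unmodelled spatial variance attenuates the estimate; 0 for `sorting`
#'   and `null`).
#' @param interaction_sd Interaction SD; `NULL` = scenario default (0.05 for
#'   `neutral_avoidance`, 1.5 for `sorting`, 0 for `null`).
#' @param site_affinity_sd SD of the species-by-site affinity logits.
#' @param hypoxia_mixing Fraction of each species' occupancy probability
#'   drawn from the bay-wide pool during hypoxic months (mass-effect
#'   mixing); `NULL` = scenario default (0.5 for `neutral_avoidance`, 0
#'   otherwise).
#' @param detection_prob Per-occurrence detection probability (Bernoulli
#'   thinning of true presence).
#' @param trough_months Months whose bottom water becomes hypoxic.
#' @param surface_do_mean,surface_do_sd Surface DO (mg/L).
#' @param bottom_do_base Bottom DO outside the trough (mg/L).
#' @param bottom_do_trough Mean bottom DO in trough months (mg/L).
#' @param do_sd DO noise SD (mg/L).
#' @param env_noise_sd Noise SD for temperature (deg C) and salinity (PSU).
#' @param monthly_n Optional vector (length = `length(months)`) of sample
#'   counts to retain per month (random subsample), emulating failed
#'   samples; `NULL` keeps all site x layer combinations.
#' @param seed Integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_sites = 14, months = 1:12, site_depths = NULL,
                              species_pool = 170,
                              scenario = c("neutral_avoidance", "sorting", "null"),
                              intercept_mean = -3.4, intercept_sd = 1.6,
                              layer_mean = 0.5, layer_sd = 0.7,
                              season_mean = -0.4, season_sd = 0.7,
                              interaction_mean = NULL, interaction_sd = NULL,
                              site_affinity_sd = 3.5, hypoxia_mixing = NULL,
                              detection_prob = 0.9,
                              trough_months = 6:9,
                              surface_do_mean = 7, surface_do_sd = 0.7,
                              bottom_do_base = 6, bottom_do_trough = 1.3,
                              do_sd = 0.5, env_noise_sd = 0.5,
                              monthly_n = NULL, seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(all(months %in% 1:12), all(trough_months %in% months),
            detection_prob >= 0, detection_prob <= 1)
  if (is.null(site_depths)) {
    site_depths <- round(seq(6, 70, length.out = n_sites), 1)
  }
  stopifnot(length(site_depths) == n_sites, all(site_depths > 0))
  if (is.null(interaction_mean)) {
    interaction_mean <- if (scenario == "neutral_avoidance") 1.5 else 0
  }
  if (is.null(interaction_sd)) {
    interaction_sd <- switch(scenario, neutral_avoidance = 0.05,
                             sorting = 1.5, null = 0)
  }
  if (is.null(hypoxia_mixing)) {
    hypoxia_mixing <- if (scenario == "neutral_avoidance") 0.5 else 0
  }
  stopifnot(hypoxia_mixing >= 0, hypoxia_mixing <= 1)
  if (scenario == "null") {
    layer_mean <- layer_sd <- season_mean <- season_sd <- 0
    interaction_mean <- interaction_sd <- 0
    hypoxia_mixing <- 0
  }
  if (!is.null(monthly_n)) stopifnot(length(monthly_n) == length(months))
  structure(list(n_sites = n_sites, months = months, site_depths = site_depths,
                 species_pool = species_pool, scenario = scenario,
                 intercept_mean = intercept_mean, intercept_sd = intercept_sd,
                 layer_mean = layer_mean, layer_sd = layer_sd,
                 season_mean = season_mean, season_sd = season_sd,
                 interaction_mean = interaction_mean,
                 interaction_sd = interaction_sd,
                 site_affinity_sd = site_affinity_sd,
                 hypoxia_mixing = hypoxia_mixing,
                 detection_prob = detection_prob,
                 trough_months = trough_months,
                 surface_do_mean = surface_do_mean,
                 surface_do_sd = surface_do_sd,
                 bottom_do_base = bottom_do_base,
                 bottom_do_trough = bottom_do_trough,
                 do_sd = do_sd, env_noise_sd = env_noise_sd,
                 monthly_n = monthly_n, seed = as.integer(seed)),
            class = "simulation_config")
}

sim_sample_grid <- function(config) {
  g <- expand.grid(site = seq_len(config$n_sites), layer = c("surface", "bottom"),
                   month = config$months, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g <- g[order(g$month, g$site, g$layer), , drop = FALSE]
  data.frame(sample_id = sprintf("S%02d_M%02d_%s", g$site, g$month,
                                 substr(g$layer, 1, 1)),
             site_id = sprintf("site%02d", g$site),
             month = as.integer(g$month),
             layer = g$layer,
             depth = config$site_depths[g$site],
             stringsAsFactors = FALSE)
}

#' Simulate the environmental table
#'
#' Deterministic seasonal curves plus Gaussian noise.  Surface DO is drawn
#' around a constant mean; bottom DO sits at `bottom_do_base` except in
#' `trough_months`, where it drops to `bottom_do_trough` (< 2 mg/L by
#' default, so the season classifier labels those months hypoxic).
#' Temperature follows an annual sinusoid peaking in August (bottom damped
#' and lagged); salinity freshens slightly at the surface in summer.  DO and
#' salinity are truncated at zero.  With all noise SDs set to zero the
#' output equals the deterministic curves.
#'
#' @param config A [simulation_config()].
#' @param metadata Sample grid; default the full grid of the config.
#' @return Environmental data frame (`sample_id`, `dissolved_oxygen`,
#'   `temperature`, `salinity`).
#' @export
simulate_environment <- function(config, metadata = sim_sample_grid(config)) {
  m <- metadata$month
  bottom <- metadata$layer == "bottom"
  do_mean <- ifelse(bottom,
                    ifelse(m %in% config$trough_months,
                           config$bottom_do_trough, config$bottom_do_base),
                    config$surface_do_mean)
  do_sd <- ifelse(bottom, config$do_sd, config$surface_do_sd)
  do <- pmax(0, rnorm(nrow(metadata), do_mean, do_sd))
  temp_mean <- ifelse(bottom,
                      15 - 4 * cospi((m - 9) / 6),
                      16 - 9 * cospi((m - 8) / 6))
  temp <- rnorm(nrow(metadata), temp_mean, config$env_noise_sd)
  sal_mean <- ifelse(bottom, 33.5, 32.5 - 1.2 * (m %in% 6:9))
  sal <- pmax(0, rnorm(nrow(metadata), sal_mean, config$env_noise_sd))
  data.frame(sample_id = metadata$sample_id,
             dissolved_oxygen = do,
             temperature = temp,
             salinity = sal,
             stringsAsFactors = FALSE)
}

#' Simulate species detections from the occurrence model
#'
#' Draws per-species coefficients from the scenario-determined normal
#' distributions, computes occurrence probabilities through the logistic
#' occurrence model (season dummy: hypoxia = 0, normoxia = 1; layer dummy:
#' surface = 0, bottom = 1 -- the generative season is membership of
#' `trough_months`), draws true presence, and thins detections with
#' `detection_prob`.
#'
#' @param config A [simulation_config()].
#' @param metadata Sample grid.
#' @return List with `detections` (long-format table of detected = TRUE
#'   rows), `coefficients` (per-species true b0, b1, b2, b3), and
#'   `site_affinity` (species x site matrix of affinity logits).
#' @export
simulate_occupancy <- function(config, metadata = sim_sample_grid(config)) {
  S <- config$species_pool
  species <- sprintf("species%03d", seq_len(S))
  b0 <- rnorm(S, config$intercept_mean, config$intercept_sd)
  b1 <- rnorm(S, config$season_mean, config$season_sd)
  b2 <- rnorm(S, config$layer_mean, config$layer_sd)
  b3 <- rnorm(S, config$interaction_mean, config$interaction_sd)
  aff <- matrix(rnorm(S * config$n_sites, 0, config$site_affinity_sd),
                S, config$n_sites,
                dimnames = list(species, sprintf("site%02d", seq_len(config$n_sites))))
  season <- as.numeric(!(metadata$month %in% config$trough_months))  # normoxia = 1
  layer <- as.numeric(metadata$layer == "bottom")
  site_idx <- match(metadata$site_id, colnames(aff))
  n <- nrow(metadata)
  eta <- outer(season, b1) + outer(layer, b2) + outer(season * layer, b3) +
    matrix(b0, n, S, byrow = TRUE) + t(aff[, site_idx, drop = FALSE])
  p_site <- plogis(eta)
  # mass-effect mixing in hypoxia: part of the occupancy probability comes
  # from the bay-wide (site-averaged) pool of the same month and layer,
  # eroding spatial structure while preserving species' overall occupancy
  grp <- paste(metadata$month, metadata$layer)
  p_bay <- (rowsum(p_site, grp) / as.vector(table(grp)[sort(unique(grp))]))[grp, , drop = FALSE]
  m_row <- config$hypoxia_mixing * (1 - season)
  p <- (1 - m_row) * p_site + m_row * p_bay
  present <- matrix(rbinom(n * S, 1L, p), n, S)
  detected <- present * matrix(rbinom(n * S, 1L, config$detection_prob), n, S)
  idx <- which(detected == 1L, arr.ind = TRUE)
  det <- data.frame(sample_id = metadata$sample_id[idx[, 1]],
                    species_name = species[idx[, 2]],
                    detected = TRUE,
                    stringsAsFactors = FALSE)
  det <- det[order(det$sample_id, det$species_name), , drop = FALSE]
  rownames(det) <- NULL
  list(detections = det,
       coefficients = data.frame(species = species, b0 = b0, b1 = b1,
                                 b2 = b2, b3 = b3, stringsAsFactors = FALSE),
       site_affinity = aff)
}

#' Simulate a full synthetic dataset
#'
#' Composes [simulate_environment()] and [simulate_occupancy()] on a common
#' sample grid (optionally subsampled to `monthly_n` samples per month) and
#' records the true parameters used.  All randomness derives from
#' `config$seed`, so re-running with the same config reproduces the tables
#' bit-exactly.
#'
#' @param config A [simulation_config()].
#' @return Object of class `simulated_dataset`: list with `detection`,
#'   `metadata`, `environment` tables, `true_parameters`, and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  md <- sim_sample_grid(config)
  if (!is.null(config$monthly_n)) {
    keep <- unlist(lapply(seq_along(config$months), function(i) {
      rows <- which(md$month == config$months[i])
      sort(sample(rows, min(config$monthly_n[i], length(rows))))
    }))
    md <- md[keep, , drop = FALSE]
    rownames(md) <- NULL
  }
  env <- simulate_environment(config, md)
  occ <- simulate_occupancy(config, md)
  structure(list(detection = occ$detections,
                 metadata = md,
                 environment = env,
                 true_parameters = list(coefficients = occ$coefficients,
                                        site_affinity = occ$site_affinity),
                 config = config),
            class = "simulated_dataset")
}

#' Write a simulated dataset in the pipeline's input dialects
#'
#' @param sim A `simulated_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named paths of the three CSV files, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(detection = file.path(dir, "detections.csv"),
             metadata = file.path(dir, "metadata.csv"),
             environment = file.path(dir, "environment.csv"))
  write.csv(sim$detection, paths["detection"], row.names = FALSE)
  write.csv(sim$metadata, paths["metadata"], row.names = FALSE)
  write.csv(sim$environment, paths["environment"], row.names = FALSE)
  invisible(paths)
}
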