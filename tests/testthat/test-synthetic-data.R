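test_that("simulated environment drives the season classifier as designed", {
  cfg <- simulation_config(seed = 31)
  sim <- simulate_dataset(cfg)
  lab <- classify_seasons(sim$environment, sim$metadata, threshold = 2)
  expect_equal(lab$month[lab$season == "hypoxia"], 6:9)

  # zero noise: the environment equals the deterministic curves
  cfg0 <- simulation_config(seed = 32, surface_do_sd = 0, do_sd = 0,
                            env_noise_sd = 0)
  sim0 <- simulate_dataset(cfg0)
  env0 <- sim0$environment
  surf <- sim0$metadata$layer == "surface"
  expect_true(all(env0$dissolved_oxygen[surf] == cfg0$surface_do_mean))
  bot_trough <- !surf & sim0$metadata$month %in% 6:9
  expect_true(all(env0$dissolved_oxygen[bot_trough] == cfg0$bottom_do_trough))
  expect_true(all(env0$dissolved_oxygen[!surf & !sim0$metadata$month %in% 6:9]
                  == cfg0$bottom_do_base))
})

test_that("simulation is bit-reproducible from (config, seed)", {
  cfg <- simulation_config(seed = 33, n_sites = 6, species_pool = 50)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$detection, s2$detection)
  expect_identical(s1$environment, s2$environment)
  expect_identical(s1$true_parameters, s2$true_parameters)
  s3 <- simulate_dataset(simulation_config(seed = 34, n_sites = 6,
                                           species_pool = 50))
  expect_false(identical(s1$detection, s3$detection))
})

test_that("null scenario occupancy matches the binomial expectation", {
  # all effects zero, intercept logit 0, no detection thinning or affinity:
  # empirical occupancy ~ 0.5 within 3 SE over ~10^4 draws
  cfg <- simulation_config(seed = 35, scenario = "null", species_pool = 40,
                           n_sites = 11, months = 1:12,
                           intercept_mean = 0, intercept_sd = 0,
                           site_affinity_sd = 0, detection_prob = 1)
  sim <- simulate_dataset(cfg)
  n_cells <- nrow(sim$metadata) * cfg$species_pool
  frac <- nrow(sim$detection) / n_cells
  se <- sqrt(0.25 / n_cells)
  expect_lt(abs(frac - 0.5), 3 * se)

  # detection thinning scales occupancy proportionally
  cfg2 <- simulation_config(seed = 35, scenario = "null", species_pool = 40,
                            n_sites = 11, months = 1:12,
                            intercept_mean = 0, intercept_sd = 0,
                            site_affinity_sd = 0, detection_prob = 0.6)
  frac2 <- nrow(simulate_dataset(cfg2)$detection) / n_cells
  expect_lt(abs(frac2 - 0.3), 3 * sqrt(0.3 * 0.7 / n_cells))
})

test_that("tables round-trip through the data-model readers", {
  cfg <- simulation_config(seed = 36, n_sites = 5, species_pool = 40)
  sim <- simulate_dataset(cfg)
  dirs <- tempfile()
  paths <- write_simulated_dataset(sim, dirs)
  det <- read_detection_table(paths["detection"])
  md <- read_sample_metadata(paths["metadata"])
  env <- read_env_table(paths["environment"])
  expect_equal(det, sim$detection, ignore_attr = TRUE)
  expect_equal(md, sim$metadata, ignore_attr = TRUE)
  expect_equal(env$dissolved_oxygen, sim$environment$dissolved_oxygen,
               tolerance = 1e-12)
  cm1 <- build_community_matrix(sim$detection, sim$metadata)
  cm2 <- build_community_matrix(det, md)
  expect_identical(cm1$occupancy, cm2$occupancy)
})

test_that("monthly_n subsampling reproduces uneven campaign sizes", {
  monthly_n <- c(23L, 22L, 22L, 21L, 20L, 20L, 18L, 21L, 20L, 2L, 15L, 22L)
  cfg <- simulation_config(seed = 37, monthly_n = monthly_n)
  sim <- simulate_dataset(cfg)
  expect_equal(unname(table(sim$metadata$month)[as.character(1:12)]),
               monthly_n, ignore_attr = TRUE)
})

test_that("sorting scenario induces a larger season:layer signal than null", {
  run <- function(scenario) {
    cfg <- simulation_config(seed = 38, scenario = scenario, n_sites = 10,
                             species_pool = 120)
    sim <- simulate_dataset(cfg)
    cm <- build_community_matrix(sim$detection, sim$metadata)
    lab <- classify_seasons(sim$environment, sim$metadata)
    d <- jaccard_matrix(cm, empty_pair = "zero")
    md <- cm$samples
    pm <- permanova(d, data.frame(season = season_of(lab, md$month),
                                  layer = factor(md$layer)),
                    c("season", "layer", "season:layer"),
                    n_perm = 49, seed = 39)
    pm$aov_table$R2[pm$aov_table$term == "season:layer"]
  }
  expect_gt(run("sorting"), run("null"))
})
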