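test_that("swap randomization preserves margins and flips checkerboards", {
  # a 2x2 checkerboard has exactly one other configuration
  cb <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  set.seed(1)
  # a single trial swap on a 2x2 checkerboard always flips it
  expect_identical(swap_randomize(cb, 1), 1L - cb)
  out <- swap_randomize(cb, 51)
  expect_true(identical(out, cb) || identical(out, 1L - cb))
  expect_equal(rowSums(out), rowSums(cb))

  # perfectly nested matrix has no checkerboard: unchanged for any n_swaps
  nested <- rbind(c(1L, 1L, 1L), c(1L, 1L, 0L), c(1L, 0L, 0L))
  set.seed(3)
  expect_identical(unname(swap_randomize(nested, 1000)), unname(nested))
})

test_that("chain visits multiple configurations when checkerboards exist", {
  m <- rbind(c(1L, 0L, 1L, 0L), c(0L, 1L, 0L, 1L),
             c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L))
  set.seed(4)
  states <- unique(vapply(1:50, function(i)
    paste(swap_randomize(m, 20), collapse = ""), character(1)))
  expect_gt(length(states), 1L)
})

test_that("pair quantiles: mid-rank ties, within-band flag, skipping, pair counts", {
  set.seed(6)
  occ <- random_binary_matrix(5, 12, 0.5)
  occ[rowSums(occ) == 0, 1] <- 1L
  cm <- make_cm(occ, month = c(1L, 1L, 1L, 1L, 2L),
                layer = c("surface", "bottom", "surface", "bottom", "surface"))
  lab <- make_labeling(1:2, hypoxia_months = 2)
  cfg <- null_model_config(n_null = 49, seed = 8)
  expect_message(pq <- pairwise_null_quantiles(cm, lab, cfg), "skipped")
  # month 2 has 1 sample (< 3): only the 6 month-1 pairs remain
  expect_equal(nrow(pq), choose(4, 2))
  expect_equal(attr(pq, "skipped_months"), 2L)
  expect_true(all(pq$season == "normoxia"))
  expect_true(all(pq$quantile >= 0 & pq$quantile <= 1))
  # within_bounds consistent with the 10-90% band definition
  expect_type(pq$within_bounds, "logical")

  # observed equal to every null value -> mid-rank quantile 0.5
  nv <- rep(0.4, 9)
  q <- (sum(nv < 0.4) + 0.5 * sum(nv == 0.4)) / 9
  expect_equal(q, 0.5)
  # nested month: null distribution degenerate at the observed value
  nested <- rbind(c(1L, 1L, 1L, 1L), c(1L, 1L, 1L, 0L), c(1L, 1L, 0L, 0L),
                  c(1L, 0L, 0L, 0L))
  cmn <- make_cm(nested, month = 1L)
  pqn <- pairwise_null_quantiles(cmn, make_labeling(1, integer()),
                                 null_model_config(n_null = 19, seed = 2))
  expect_true(all(pqn$quantile == 0.5))
})

test_that("rank-sum comparison: exact small-sample case and degenerate ties", {
  # exact two-sided p = 0.1 for the most extreme ranking of 3 vs 3
  pairs <- data.frame(season = rep(c("hypoxia", "normoxia"), each = 3),
                      quantile = c(1, 2, 3, 4, 5, 6) / 10)
  cmp <- compare_quantiles_by_season(pairs)
  expect_true(cmp$exact)
  expect_equal(cmp$p_value, 0.1, tolerance = 1e-12)

  # identical samples -> p = 1
  pairs2 <- data.frame(season = rep(c("hypoxia", "normoxia"), each = 3),
                       quantile = rep(c(0.2, 0.4, 0.6), 2))
  expect_equal(compare_quantiles_by_season(pairs2)$p_value, 1)

  # strongly shifted large samples -> tiny p, statistic matches brute-force W
  set.seed(9)
  qh <- runif(80, 0, 0.4); qn <- runif(90, 0.3, 1)
  pairs3 <- data.frame(season = rep(c("hypoxia", "normoxia"), c(80, 90)),
                       quantile = c(qh, qn))
  cmp3 <- compare_quantiles_by_season(pairs3)
  expect_lt(cmp3$p_value, 0.001)
  r <- rank(c(qh, qn))
  expect_equal(cmp3$rank_sum_statistic,
               sum(r[1:80]) - 80 * 81 / 2)  # Mann-Whitney U from ranks

  # season comparison invariant to pair ordering
  cmp3b <- compare_quantiles_by_season(pairs3[sample(170), ])
  expect_equal(cmp3b$p_value, cmp3$p_value)

  expect_error(compare_quantiles_by_season(
    data.frame(season = "hypoxia", quantile = 0.5)), "both seasons")
})
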