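test_that("Jaccard dissimilarity matches the set definition", {
  occ <- rbind(a = c(1L, 1L, 0L), b = c(1L, 0L, 1L), c = c(1L, 1L, 0L),
               d = c(0L, 0L, 1L))
  colnames(occ) <- c("x", "y", "z")
  d <- as.matrix(jaccard_matrix(occ))
  expect_equal(d["a", "c"], 0)        # identical rows
  expect_equal(d["a", "d"], 1)        # disjoint rows
  expect_equal(d["a", "b"], 2 / 3)    # 1 shared, union 3

  # hand-computed pairwise oracle on random fixtures
  set.seed(21)
  m <- random_binary_matrix(7, 11, 0.4)
  m[rowSums(m) == 0, 1] <- 1L
  d2 <- as.matrix(jaccard_matrix(m))
  for (i in 1:6) for (j in (i + 1):7) {
    inter <- sum(m[i, ] & m[j, ]); uni <- sum(m[i, ] | m[j, ])
    expect_equal(d2[i, j], 1 - inter / uni)
  }

  # empty-union handling
  z <- rbind(c(0L, 0L), c(0L, 0L), c(1L, 0L))
  expect_error(jaccard_matrix(z), "empty union")
  expect_equal(as.matrix(jaccard_matrix(z, empty_pair = "zero"))[1, 2], 0)
})

test_that("Jaccard satisfies the triangle inequality on random binary fixtures", {
  set.seed(31)
  for (rep in 1:20) {
    m <- random_binary_matrix(5, 8, runif(1, 0.2, 0.7))
    m[rowSums(m) == 0, sample(8, 1)] <- 1L
    d <- as.matrix(jaccard_matrix(m))
    for (i in 1:5) for (j in 1:5) for (k in 1:5) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  }
})

test_that("Euclidean distances match a brute-force double loop", {
  expect_equal(as.matrix(euclidean_matrix(rbind(c(0, 0), c(3, 4))))[1, 2], 5)
  set.seed(41)
  x <- matrix(rnorm(30), 10, 3)
  d <- as.matrix(euclidean_matrix(x))
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(d[i, j], sqrt(sum((x[i, ] - x[j, ])^2)), tolerance = 1e-12)
  }
  expect_equal(as.matrix(euclidean_matrix(rbind(x[1, ], x[1, ])))[1, 2], 0)
  expect_error(euclidean_matrix(cbind(1:5, rep(2, 5)), standardize = TRUE),
               "constant")
  # distance matrix TSV round trip
  f <- tempfile(fileext = ".tsv")
  rownames(x) <- sprintf("s%d", 1:10)
  write_distance_tsv(dist(x), f)
  expect_equal(as.matrix(read_distance_tsv(f)), as.matrix(dist(x)),
               tolerance = 1e-12)
})

test_that("NMDS recovers embeddable configurations and is rank-invariant", {
  set.seed(9)
  pts <- matrix(rnorm(60), 20, 3)
  ord <- nmds(dist(pts), k = 3, n_restarts = 5, seed = 3)
  expect_lt(ord$stress, 0.01)
  expect_true(ord$converged)
  # coordinates centred at the origin
  expect_equal(colMeans(ord$coordinates), rep(0, 3),
               ignore_attr = TRUE, tolerance = 1e-8)
  # stress depends only on the rank order of dissimilarities
  set.seed(8)
  p8 <- matrix(rnorm(24), 8, 3)
  d8 <- dist(p8); m8 <- as.matrix(d8)
  s0 <- nmds(d8, k = 2, n_restarts = 30, seed = 2)$stress
  expect_gt(s0, 0.01)  # genuinely non-embeddable in 2 dimensions
  for (tr in list(function(d) d^1.5, function(d) exp(d) - 1,
                  function(d) 2 * d + 0.3 * d^2)) {
    st <- nmds(as.dist(tr(m8)), k = 2, n_restarts = 30, seed = 2)$stress
    expect_equal(st, s0, tolerance = 1e-6)
  }
  # best-of-restarts: returned stress is the minimum over restarts
  expect_equal(ord$stress, min(ord$restart_stress))
})

test_that("centroid distance is exact on hand cases and rotation-invariant", {
  coords <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 2, 2), c(1, 2, 2))
  g <- c("A", "A", "B", "B")
  expect_equal(centroid_distance(coords, g, "A", "B"), 3)
  expect_equal(centroid_distance(coords, g, "A", "A"), 0)
  expect_error(centroid_distance(coords, g, "A", "C"), "empty group")
  set.seed(12)
  x <- matrix(rnorm(30), 10, 3)
  g2 <- rep(c("p", "q"), 5)
  d0 <- centroid_distance(x, g2, "p", "q")
  rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_equal(centroid_distance(x %*% rot, g2, "p", "q"), d0,
               tolerance = 1e-10)
  # first-dims restriction
  expect_equal(centroid_distance(coords, g, "A", "B", dims = 2), sqrt(5))
})
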