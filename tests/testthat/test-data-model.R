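test_that("read_detection_table parses counts, flags, and bad input", {
  f <- write_lines_tmp(c("sample_id,species_name,count",
                         "S1,Konosirus punctatus,12",
                         "S1,Engraulis japonicus,0"))
  rec <- read_detection_table(f)
  expect_equal(rec$detected, c(TRUE, FALSE))
  expect_equal(rec$species_name[1], "Konosirus punctatus")

  f2 <- write_lines_tmp(c("sample_id\tspecies_name\tdetected",
                          "S1\tA\tTRUE"), ext = ".tsv")
  expect_true(read_detection_table(f2)$detected)

  empty <- write_lines_tmp("sample_id,species_name,count")
  expect_equal(nrow(read_detection_table(empty)), 0L)

  bad <- write_lines_tmp(c("sample_id,species_name,count", "S1,A,lots"))
  expect_error(read_detection_table(bad), "non-numeric")
  nocol <- write_lines_tmp(c("sample_id,name", "S1,A"))
  expect_error(read_detection_table(nocol), "column")
})

test_that("species filter precedence, arithmetic identity, unknown names", {
  rec <- data.frame(sample_id = "S1",
                    species_name = c("a", "b", "c", "d", "e"),
                    detected = TRUE, stringsAsFactors = FALSE)
  # one species in both lists is attributed to the first criterion only
  res <- apply_species_filters(rec, unmatched_names = "b",
                               excluded_habitat = c("b"))
  expect_equal(res$report$n_removed_name, 1L)
  expect_equal(res$report$n_removed_habitat, 0L)
  expect_equal(res$report$n_retained, 4L)

  # identity with empty lists
  res0 <- apply_species_filters(rec)
  expect_equal(res0$report,
               list(n_detected = 5L, n_removed_name = 0L,
                    n_removed_habitat = 0L, n_retained = 5L))
  expect_identical(res0$records, rec)

  expect_message(apply_species_filters(rec, unmatched_names = "zz"),
                 "not present")

  # arithmetic identity on random inputs
  set.seed(11)
  for (i in 1:20) {
    sp <- sample(letters, 15)
    r <- data.frame(sample_id = "S", species_name = sp, detected = TRUE)
    u <- sample(letters, 5); h <- sample(letters, 5)
    rep_i <- apply_species_filters(r, u, h)$report
    expect_equal(rep_i$n_retained,
                 rep_i$n_detected - rep_i$n_removed_name - rep_i$n_removed_habitat)
  }
})

test_that("community matrix collapses duplicates, drops empty species, round-trips", {
  md <- data.frame(sample_id = c("S1", "S2", "S3"),
                   site_id = c("a", "b", "c"), month = 1L,
                   layer = "surface", depth = 10)
  rec <- data.frame(
    sample_id = c("S1", "S1", "S2", "S3", "S1"),
    species_name = c("x", "x", "y", "x", "z"),
    detected = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  cm <- build_community_matrix(rec, md)
  # manual tabulation: z never detected -> dropped; duplicate S1/x collapses
  expect_equal(cm$occupancy,
               matrix(c(1L, 0L, 1L, 0L, 1L, 0L), 3, 2,
                      dimnames = list(c("S1", "S2", "S3"), c("x", "y"))))
  expect_error(build_community_matrix(
    data.frame(sample_id = "S9", species_name = "x", detected = TRUE), md),
    "unknown sample_id")

  # idempotence: rebuild from the long export
  set.seed(3)
  occ <- random_binary_matrix(6, 9)
  cm2 <- make_cm(occ)
  cm3 <- build_community_matrix(community_long(cm2), cm2$samples)
  keep <- colnames(occ)[colSums(occ) > 0]
  expect_identical(cm3$occupancy, cm2$occupancy[, keep])
})

test_that("top-species selection uses ceiling and lexicographic ties", {
  set.seed(7)
  counts <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
  occ <- matrix(0L, 10, 10,
                dimnames = list(sprintf("s%02d", 1:10), letters[1:10]))
  for (j in 1:10) occ[seq_len(counts[j]), j] <- 1L
  cm <- make_cm(occ)
  expect_equal(select_top_species(cm, 0.3), c("a", "b", "c"))
  expect_equal(length(select_top_species(cm, 1.0)), 10L)
  # ceiling property across fractions
  for (f in c(0.01, 0.1, 0.15, 0.34, 0.5, 0.99, 1)) {
    expect_length(select_top_species(cm, f), ceiling(f * 10))
  }
  # tie broken alphabetically: two species with equal counts
  occ2 <- cbind(b = c(1L, 1L, 0L), a = c(1L, 1L, 0L), c = c(1L, 0L, 0L))
  rownames(occ2) <- c("s1", "s2", "s3")
  expect_equal(select_top_species(make_cm(occ2), 0.3), "a")
  expect_error(select_top_species(make_cm(occ[, 0, drop = FALSE]), 0.5),
               "no species")
})

test_that("richness is row sums and conserves total occurrences", {
  occ <- rbind(c(0L, 0L, 0L, 0L), c(1L, 0L, 1L, 1L))
  cm <- make_cm(occ)
  expect_equal(unname(compute_richness(cm)), c(0L, 3L))
  set.seed(5)
  m <- random_binary_matrix(8, 12)
  expect_equal(sum(compute_richness(make_cm(m))), sum(m))
})

test_that("metadata validation rejects malformed tables", {
  md <- data.frame(sample_id = c("a", "b"), site_id = c("s1", "s2"),
                   month = c(1L, 13L), layer = "surface", depth = 10)
  expect_error(build_community_matrix(
    data.frame(sample_id = "a", species_name = "x", detected = TRUE), md),
    "month")
  md$month <- c(1L, 2L); md$depth <- c(10, 300)
  expect_error(hypoxbeta:::validate_metadata(md),"depth")
  md$depth <- 10; md$layer <- c("surface", "middle")
  expect_error(hypoxbeta:::validate_metadata(md),"layer")
})
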