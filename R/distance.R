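#' Pairwise Jaccard dissimilarity on presence/absence data
#'
#' For two samples with species presence sets A and B,
#' `d = 1 - |A intersect B| / |A union B|`.  Pairs in which both samples are
#' empty (empty union) are undefined; by default this is an error, or they
#' can be set to 0.
#'
#' @param cm A `community_matrix` or binary matrix (samples in rows).
#' @param empty_pair `"error"` (default) or `"zero"` for pairs with empty
#'   union.
#' @return A [stats::dist] object labelled with sample ids.
#' @export
jaccard_matrix <- function(cm, empty_pair = c("error", "zero")) {
  empty_pair <- match.arg(empty_pair)
  occ <- occupancy_of(cm)
  zero_rows <- rowSums(occ) == 0
  if (sum(zero_rows) >= 2 && empty_pair == "error") {
    stop("pairs of samples with no species have an empty union; ",
         "set empty_pair = 'zero' to define their dissimilarity as 0")
  }
  d <- suppressWarnings(vegan::vegdist(occ, method = "jaccard", binary = TRUE))
  if (anyNA(d)) d[is.na(d)] <- 0  # only empty-union pairs produce NA
  d
}

#' Pairwise Euclidean distances with optional standardization
#'
#' @param x Numeric matrix or data frame, samples in rows.
#' @param standardize Centre and scale each variable to unit variance first.
#' @return A [stats::dist] object.
#' @export
euclidean_matrix <- function(x, standardize = FALSE) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("distance input contains missing values")
  if (standardize) {
    sds <- apply(x, 2, sd)
    if (any(sds == 0)) {
      stop("constant variable(s) cannot be standardized: ",
           paste(colnames(x)[sds == 0], collapse = ", "))
    }
    x <- scale(x)
  }
  dist(x)
}

#' Write / read a distance matrix as square TSV
#'
#' @param d A [stats::dist] object.
#' @param path Output path.
#' @return `path` (write) or a `dist` (read), invisibly for write.
#' @export
write_distance_tsv <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- read.csv(path, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  as.dist(m)
}
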