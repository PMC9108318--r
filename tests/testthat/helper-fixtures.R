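# Small in-code fixtures shared across the suite.

# community matrix from an explicit 0/1 matrix; months/layers recycled
make_cm <- function(occ, month = 1L, layer = "surface", site = NULL,
                    depth = 10) {
  n <- nrow(occ)
  if (is.null(rownames(occ))) rownames(occ) <- sprintf("s%02d", seq_len(n))
  if (is.null(colnames(occ))) colnames(occ) <- sprintf("sp%02d", seq_len(ncol(occ)))
  month <- rep_len(month, n)
  layer <- rep_len(layer, n)
  if (is.null(site)) site <- paste0("site", seq_len(n))
  md <- data.frame(sample_id = rownames(occ), site_id = rep_len(site, n),
                   month = as.integer(month), layer = layer,
                   depth = rep_len(depth, n), stringsAsFactors = FALSE)
  storage.mode(occ) <- "integer"
  structure(list(occupancy = occ, samples = md), class = "community_matrix")
}

# season labeling without going through DO values
make_labeling <- function(months, hypoxia_months, threshold = 2) {
  structure(data.frame(month = months,
                       min_do = ifelse(months %in% hypoxia_months, 1, 5),
                       season = ifelse(months %in% hypoxia_months,
                                       "hypoxia", "normoxia"),
                       stringsAsFactors = FALSE),
            class = c("season_labeling", "data.frame"), threshold = threshold)
}

random_binary_matrix <- function(nr, nc, p = 0.3) {
  m <- matrix(rbinom(nr * nc, 1L, p), nr, nc)
  rownames(m) <- sprintf("s%02d", seq_len(nr))
  colnames(m) <- sprintf("sp%02d", seq_len(nc))
  storage.mode(m) <- "integer"
  m
}

write_lines_tmp <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
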