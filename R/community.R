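#' Filter detected species against curated exclusion lists
#'
#' Removes detections of species whose names could not be matched against a
#' reference database (first criterion) and of species whose known habitat
#' lies outside the study system (second criterion).  The first filter takes
#' precedence: a species listed in both sets is counted under the name filter
#' only.  Counts in the returned report are numbers of unique species.
#'
#' @param records Detection data frame as from [read_detection_table()].
#' @param unmatched_names Character vector of species names failing the
#'   database name match.
#' @param excluded_habitat Character vector of species known not to occur in
#'   the study area.
#' @return A list with `records` (filtered detections) and `report`, a list
#'   with counts `n_detected`, `n_removed_name`, `n_removed_habitat`,
#'   `n_retained` satisfying
#'   `n_retained == n_detected - n_removed_name - n_removed_habitat`.
#' @export
apply_species_filters <- function(records, unmatched_names = character(),
                                  excluded_habitat = character()) {
  stopifnot(is.data.frame(records))
  detected <- unique(records$species_name)
  rm_name <- intersect(detected, unmatched_names)
  rm_hab <- setdiff(intersect(detected, excluded_habitat), rm_name)
  unknown <- setdiff(union(unmatched_names, excluded_habitat), detected)
  if (length(unknown)) {
    message(length(unknown), " filter-list name(s) not present among detections; ignored")
  }
  keep <- !(records$species_name %in% c(rm_name, rm_hab))
  report <- list(n_detected = length(detected),
                 n_removed_name = length(rm_name),
                 n_removed_habitat = length(rm_hab),
                 n_retained = length(detected) - length(rm_name) - length(rm_hab))
  list(records = records[keep, , drop = FALSE], report = report)
}

#' Build a binary community matrix from detections and metadata
#'
#' Collapses (possibly duplicated) detection records to a samples-by-species
#' presence/absence matrix aligned with the metadata rows.  Samples listed in
#' the metadata but absent from the detections get all-zero rows; species
#' never detected in any retained sample are dropped.  Species columns are
#' ordered alphabetically for determinism.
#'
#' @param records Detection data frame (`sample_id`, `species_name`,
#'   `detected`).
#' @param metadata Sample metadata data frame as from
#'   [read_sample_metadata()].
#' @return An object of class `community_matrix`: a list with `occupancy`
#'   (integer 0/1 matrix, rownames = sample ids) and `samples` (the metadata,
#'   row order matching the matrix).
#' @export
build_community_matrix <- function(records, metadata) {
  validate_metadata(metadata)
  pos <- records[records$detected, , drop = FALSE]
  unknown <- setdiff(pos$sample_id, metadata$sample_id)
  if (length(unknown)) {
    stop("detection records reference unknown sample_id(s): ",
         paste(head(unknown, 5), collapse = ", "))
  }
  species <- sort(unique(pos$species_name))
  occ <- matrix(0L, nrow = nrow(metadata), ncol = length(species),
                dimnames = list(metadata$sample_id, species))
  if (nrow(pos)) {
    occ[cbind(match(pos$sample_id, metadata$sample_id),
              match(pos$species_name, species))] <- 1L
  }
  structure(list(occupancy = occ, samples = metadata),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("community_matrix:", nrow(x$occupancy), "samples x",
      ncol(x$occupancy), "species;",
      sum(x$occupancy), "occurrences\n")
  invisible(x)
}

#' Export a community matrix in long format
#'
#' One row per occurrence (`detected = TRUE`); rebuilding with
#' [build_community_matrix()] from this export reproduces the matrix exactly.
#'
#' @param cm A `community_matrix`.
#' @return Data frame with columns `sample_id`, `species_name`, `detected`.
#' @export
community_long <- function(cm) {
  idx <- which(cm$occupancy == 1L, arr.ind = TRUE)
  out <- data.frame(sample_id = rownames(cm$occupancy)[idx[, 1]],
                    species_name = colnames(cm$occupancy)[idx[, 2]],
                    detected = rep(TRUE, nrow(idx)),
                    stringsAsFactors = FALSE)
  out[order(out$sample_id, out$species_name), , drop = FALSE]
}

#' Write a community matrix as wide CSV
#'
#' @param cm A `community_matrix`.
#' @param path Output file; first column `sample_id`, one column per species.
#' @export
write_community_matrix <- function(cm, path) {
  df <- data.frame(sample_id = rownames(cm$occupancy), cm$occupancy,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-sample species richness
#'
#' @param cm A `community_matrix` (or binary matrix).
#' @return Named integer vector of row sums of the occupancy matrix.
#' @export
compute_richness <- function(cm) {
  occ <- occupancy_of(cm)
  rs <- rowSums(occ)
  storage.mode(rs) <- "integer"
  rs
}

#' Most frequently observed species
#'
#' Returns the `ceiling(fraction * n_species)` species with the highest
#' occurrence counts; ties are broken alphabetically so the selection is
#' deterministic.
#'
#' @param cm A `community_matrix` (or binary matrix).
#' @param fraction Fraction of the species pool to keep, in (0, 1].
#' @return Character vector of species names, most frequent first.
#' @export
select_top_species <- function(cm, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1)
  occ <- occupancy_of(cm)
  if (ncol(occ) == 0L) stop("community matrix has no species")
  counts <- colSums(occ)
  n_take <- ceiling(fraction * ncol(occ))
  ord <- order(-counts, colnames(occ))
  colnames(occ)[ord][seq_len(n_take)]
}

occupancy_of <- function(x) {
  occ <- if (inherits(x, "community_matrix")) x$occupancy else as.matrix(x)
  if (!all(occ %in% c(0L, 1L))) stop("occupancy entries must be 0/1")
  occ
}
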