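#' Read a long-format species detection table
#'
#' Reads a delimited text file with one row per (sample, species) detection.
#' The file must have a header with columns `sample_id`, `species_name`, and
#' either `detected` (logical or 0/1) or `count` (non-negative reads); counts
#' greater than zero are collapsed to presence, mirroring the treatment of
#' metabarcoding read counts as presence/absence.
#'
#' @param path Path to a UTF-8 CSV or TSV file.
#' @param delim Field delimiter; `NULL` (default) auto-detects `,` vs tab from
#'   the header line.
#' @return A data frame with columns `sample_id`, `species_name`, `detected`
#'   (logical).
#' @export
read_detection_table <- function(path, delim = NULL) {
  df <- read_delimited(path, delim)
  need <- c("sample_id", "species_name")
  if (!all(need %in% names(df))) {
    stop("detection table must have columns 'sample_id' and 'species_name'")
  }
  if ("detected" %in% names(df)) {
    det <- df$detected
    if (is.character(det)) det <- toupper(trimws(det)) %in% c("TRUE", "T", "1")
    detected <- as.logical(det)
    if (anyNA(detected)) stop("column 'detected' is not interpretable as logical")
  } else if ("count" %in% names(df)) {
    cnt <- suppressWarnings(as.numeric(df$count))
    if (anyNA(cnt)) stop("column 'count' contains non-numeric values")
    detected <- cnt > 0
  } else {
    stop("detection table must have a 'detected' or 'count' column")
  }
  out <- data.frame(sample_id = as.character(df$sample_id),
                    species_name = as.character(df$species_name),
                    detected = detected,
                    stringsAsFactors = FALSE)
  if (nrow(out) > 0 && (any(!nzchar(out$sample_id)) || any(!nzchar(out$species_name)))) {
    stop("sample_id and species_name must be nonempty")
  }
  out
}

#' Read a sample metadata table
#'
#' Expects columns `sample_id`, `site_id`, `month` (1-12), `layer`
#' (`surface`/`bottom`) and `depth` (site depth in metres, in (0, 200]).
#' Each (site, month, layer) combination must identify a unique sample.
#'
#' @inheritParams read_detection_table
#' @return Data frame of validated sample metadata.
#' @export
read_sample_metadata <- function(path, delim = NULL) {
  df <- read_delimited(path, delim)
  need <- c("sample_id", "site_id", "month", "layer", "depth")
  if (!all(need %in% names(df))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(sample_id = as.character(df$sample_id),
                    site_id = as.character(df$site_id),
                    month = as.integer(df$month),
                    layer = as.character(df$layer),
                    depth = as.numeric(df$depth),
                    stringsAsFactors = FALSE)
  validate_metadata(out)
  out
}

validate_metadata <- function(md) {
  if (anyNA(md$month) || any(md$month < 1L | md$month > 12L)) {
    stop("month must be an integer in 1-12")
  }
  if (!all(md$layer %in% c("surface", "bottom"))) {
    stop("layer must be 'surface' or 'bottom'")
  }
  if (anyNA(md$depth) || any(md$depth <= 0 | md$depth > 200)) {
    stop("depth must lie in (0, 200] metres")
  }
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  key <- paste(md$site_id, md$month, md$layer)
  if (anyDuplicated(key)) stop("(site_id, month, layer) must identify a unique sample")
  invisible(md)
}

#' Read a per-sample environmental table
#'
#' Expects columns `sample_id`, `dissolved_oxygen` (mg/L, >= 0),
#' `temperature` (degrees C) and `salinity` (PSU, >= 0); missing values are
#' rejected since samples lacking environmental data are excluded upstream.
#'
#' @inheritParams read_detection_table
#' @return Data frame of validated environmental measurements.
#' @export
read_env_table <- function(path, delim = NULL) {
  df <- read_delimited(path, delim)
  need <- c("sample_id", "dissolved_oxygen", "temperature", "salinity")
  if (!all(need %in% names(df))) {
    stop("environment table must have columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(sample_id = as.character(df$sample_id),
                    dissolved_oxygen = as.numeric(df$dissolved_oxygen),
                    temperature = as.numeric(df$temperature),
                    salinity = as.numeric(df$salinity),
                    stringsAsFactors = FALSE)
  if (anyNA(out[-1])) stop("environment table contains missing values")
  if (any(out$dissolved_oxygen < 0) || any(out$salinity < 0)) {
    stop("dissolved_oxygen and salinity must be non-negative")
  }
  out
}

#' Read a species filter list
#'
#' One species name per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to a plain-text list.
#' @return Character vector of species names.
#' @export
read_species_list <- function(path) {
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

read_delimited <- function(path, delim = NULL) {
  if (is.null(delim)) {
    header <- readLines(path, n = 1L, warn = FALSE)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  read.csv(path, sep = delim, stringsAsFactors = FALSE, check.names = TRUE,
           fileEncoding = "UTF-8")
}
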