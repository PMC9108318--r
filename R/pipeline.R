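#' Pipeline configuration
#'
#' Bundles inputs and stage parameters for [run_pipeline()].  The three
#' table arguments may be file paths (CSV/TSV as documented in the readers)
#' or in-memory data frames; the filter lists may be paths to plain-text
#' lists or character vectors.
#'
#' @param detection Detection table (path or data frame).
#' @param metadata Sample metadata (path or data frame).
#' @param environment Environmental table (path or data frame).
#' @param unmatched_names,excluded_habitat Species filter lists (path or
#'   character vector).
#' @param threshold Hypoxia threshold, mg/L.
#' @param min_samples_per_month Months with fewer samples are excluded from
#'   ordination, PERMANOVA, and null-model stages.
#' @param nmds List: `k`, `n_restarts`, `tol`.
#' @param permanova List: `n_perm`.
#' @param nullmodel A [null_model_config()].
#' @param top_species_fraction Fraction of most frequent species entering
#'   the occurrence model.
#' @param seed Master seed; every stochastic stage consumes a sub-seed
#'   derived from it by stage-name hashing.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(detection, metadata, environment,
                            unmatched_names = character(),
                            excluded_habitat = character(),
                            threshold = 2, min_samples_per_month = 3,
                            nmds = list(k = 3, n_restarts = 20, tol = 1e-6),
                            permanova = list(n_perm = 999),
                            nullmodel = null_model_config(),
                            top_species_fraction = 0.10,
                            seed = 1) {
  structure(list(detection = detection, metadata = metadata,
                 environment = environment,
                 unmatched_names = unmatched_names,
                 excluded_habitat = excluded_habitat,
                 threshold = threshold,
                 min_samples_per_month = min_samples_per_month,
                 nmds = nmds, permanova = permanova, nullmodel = nullmodel,
                 top_species_fraction = top_species_fraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.character(p) && length(p) == 1 && !file.exists(p)) {
      cand <- file.path(base, p)
      if (file.exists(cand)) return(cand)
    }
    p
  }
  args <- y
  for (k in c("detection", "metadata", "environment",
              "unmatched_names", "excluded_habitat")) {
    if (!is.null(args[[k]])) args[[k]] <- resolve(args[[k]])
  }
  if (!is.null(args$nullmodel)) {
    args$nullmodel <- do.call(null_model_config, args$nullmodel)
  }
  do.call(pipeline_config, args)
}

resolve_table <- function(x, reader) if (is.character(x)) reader(x) else x
resolve_list <- function(x) if (is.character(x) && length(x) == 1 &&
                                 file.exists(x)) read_species_list(x) else x

#' Run the full community-assembly analysis pipeline
#'
#' Executes, in order: ingest and validation; species filtering; community
#' matrix construction; season classification from dissolved oxygen;
#' richness summaries and the Poisson richness GLMM; PCA of the
#' environmental variables; PERMANOVA of the environment (Euclidean,
#' standardized) with season, layer, and their interaction; Jaccard
#' dissimilarities, NMDS, and surface-bottom centroid distances per season;
#' PERMANOVAs of composition (season x layer, and layer x site depth); the
#' per-month fixed-fixed null model with the between-season quantile
#' comparison; and the hierarchical occurrence GLMMs with their
#' likelihood-ratio test.  Months with fewer than `min_samples_per_month`
#' samples are excluded from distance-based stages and the null model.
#'
#' A failing stage is recorded as `status = "failed"` with the error message
#' and downstream stages that depend on it are marked skipped; independent
#' stages still run.
#'
#' @param config A [pipeline_config()].
#' @return List of class `study_report`; each element has `status`
#'   (`"ok"`, `"failed"`, or `"skipped"`) plus stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list()
  stage <- function(name, deps = character(), expr) {
    failed_dep <- deps[vapply(deps, function(d)
      !identical(report[[d]]$status, "ok"), logical(1))]
    report[[name]] <<- if (length(failed_dep)) {
      list(status = "skipped",
           reason = paste("dependency failed:", paste(failed_dep, collapse = ", ")))
    } else {
      tryCatch(c(list(status = "ok"), expr()),
               error = function(e) list(status = "failed",
                                        reason = conditionMessage(e)))
    }
    invisible(NULL)
  }

  env_store <- new.env(parent = emptyenv())

  stage("ingest", character(), function() {
    env_store$detection <- resolve_table(config$detection, read_detection_table)
    env_store$metadata <- resolve_table(config$metadata, read_sample_metadata)
    env_store$environment <- resolve_table(config$environment, read_env_table)
    validate_metadata(env_store$metadata)
    list(n_records = nrow(env_store$detection),
         n_samples = nrow(env_store$metadata))
  })

  stage("filter", "ingest", function() {
    fl <- apply_species_filters(env_store$detection,
                                resolve_list(config$unmatched_names),
                                resolve_list(config$excluded_habitat))
    env_store$records <- fl$records
    list(report = fl$report)
  })

  stage("community_matrix", "filter", function() {
    cm <- build_community_matrix(env_store$records, env_store$metadata)
    env_store$cm <- cm
    list(n_samples = nrow(cm$occupancy), n_species = ncol(cm$occupancy))
  })

  stage("seasons", "ingest", function() {
    lab <- classify_seasons(env_store$environment, env_store$metadata,
                            config$threshold)
    env_store$labeling <- lab
    list(labels = as.data.frame(lab), threshold = config$threshold)
  })

  stage("richness", c("community_matrix", "seasons"), function() {
    summary_tab <- summarize_richness(env_store$cm, env_store$labeling)
    fit <- fit_richness_glmm(env_store$cm, env_store$labeling)
    list(summary = summary_tab, glmm = fit)
  })

  # distance-based stages operate on months with enough samples
  subset_months <- function() {
    md <- env_store$metadata
    keep_months <- as.integer(names(which(table(md$month) >= config$min_samples_per_month)))
    md$sample_id[md$month %in% keep_months]
  }

  stage("pca", c("ingest", "seasons"), function() {
    env <- env_store$environment
    x <- as.matrix(env[, c("dissolved_oxygen", "temperature", "salinity")])
    rownames(x) <- env$sample_id
    p <- run_pca(x, standardize = TRUE)
    env_store$env_matrix <- x
    list(variance_fraction = p$variance_fraction, pca = p)
  })

  stage("permanova_environment", c("pca", "seasons"), function() {
    ids <- subset_months()
    md <- env_store$metadata
    keep <- md$sample_id %in% ids
    x <- env_store$env_matrix[md$sample_id[keep], , drop = FALSE]
    d <- euclidean_matrix(x, standardize = TRUE)
    dat <- data.frame(
      season = season_of(env_store$labeling, md$month[keep]),
      layer = factor(md$layer[keep], levels = c("surface", "bottom")))
    res <- permanova(d, dat, c("season", "layer", "season:layer"),
                     n_perm = config$permanova$n_perm,
                     seed = stage_seed(config$seed, "permanova_environment"))
    list(table = res$aov_table)
  })

  stage("ordination", c("community_matrix", "seasons"), function() {
    ids <- subset_months()
    cm <- env_store$cm
    keep <- cm$samples$sample_id %in% ids
    occ <- cm$occupancy[keep, , drop = FALSE]
    d <- jaccard_matrix(occ, empty_pair = "zero")
    ord <- nmds(d, k = config$nmds$k, n_restarts = config$nmds$n_restarts,
                tol = config$nmds$tol,
                seed = stage_seed(config$seed, "ordination"))
    md <- cm$samples[keep, , drop = FALSE]
    seas <- season_of(env_store$labeling, md$month)
    cd <- vapply(c("hypoxia", "normoxia"), function(s) {
      centroid_distance(ord$coordinates[seas == s, , drop = FALSE],
                        md$layer[seas == s], "surface", "bottom")
    }, numeric(1))
    env_store$jaccard <- d
    env_store$ord_meta <- md
    list(stress = ord$stress, k = ord$k, converged = ord$converged,
         centroid_distance = cd, ordination = ord)
  })

  stage("permanova_composition", c("ordination", "seasons"), function() {
    md <- env_store$ord_meta
    dat <- data.frame(
      season = season_of(env_store$labeling, md$month),
      layer = factor(md$layer, levels = c("surface", "bottom")))
    res <- permanova(env_store$jaccard, dat, c("season", "layer", "season:layer"),
                     n_perm = config$permanova$n_perm,
                     seed = stage_seed(config$seed, "permanova_composition"))
    list(table = res$aov_table)
  })

  stage("permanova_layer_depth", "ordination", function() {
    md <- env_store$ord_meta
    dat <- data.frame(
      layer = factor(md$layer, levels = c("surface", "bottom")),
      depth = md$depth)
    res <- permanova(env_store$jaccard, dat, c("layer", "depth", "layer:depth"),
                     n_perm = config$permanova$n_perm,
                     seed = stage_seed(config$seed, "permanova_layer_depth"))
    list(table = res$aov_table)
  })

  stage("null_model", c("community_matrix", "seasons"), function() {
    nm_config <- config$nullmodel
    nm_config$min_samples_per_month <- config$min_samples_per_month
    nm_config$seed <- stage_seed(config$seed, "null_model")
    pairs <- pairwise_null_quantiles(env_store$cm, env_store$labeling, nm_config)
    cmp <- compare_quantiles_by_season(pairs)
    env_store$pairs <- pairs
    list(n_pairs = nrow(pairs),
         n_pairs_by_season = table(pairs$season),
         within_bounds_by_season = tapply(pairs$within_bounds, pairs$season, sum),
         mean_quantile_by_season = tapply(pairs$quantile, pairs$season, mean),
         comparison = cmp,
         pairs = pairs)
  })

  stage("occurrence_glmm", c("community_matrix", "seasons"), function() {
    sp <- select_top_species(env_store$cm, config$top_species_fraction)
    full <- fit_occurrence_glmm(env_store$cm, env_store$labeling, sp,
                                random_interaction = TRUE)
    reduced <- fit_occurrence_glmm(env_store$cm, env_store$labeling, sp,
                                   random_interaction = FALSE)
    list(species = sp, full = full, reduced = reduced,
         lrt = likelihood_ratio_test(full, reduced))
  })

  structure(report, class = "study_report", seed = config$seed)
}

#' Season-by-layer species richness summary
#'
#' Mean and sample standard deviation (n - 1 denominator) of per-sample
#' richness in each season x layer cell; cells with a single sample get
#' `NA` SD.
#'
#' @param cm A `community_matrix`.
#' @param labeling A `season_labeling`.
#' @return Data frame with `season`, `layer`, `n`, `mean`, `sd`.
#' @export
summarize_richness <- function(cm, labeling) {
  rich <- compute_richness(cm)
  season <- season_of(labeling, cm$samples$month)
  layer <- factor(cm$samples$layer, levels = c("surface", "bottom"))
  out <- expand.grid(season = levels(season), layer = levels(layer),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- lapply(seq_len(nrow(out)), function(i) {
    v <- rich[season == out$season[i] & layer == out$layer[i]]
    data.frame(n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else NA_real_)
  })
  cbind(out, do.call(rbind, cells))
}

#' Write a study report to disk
#'
#' Writes `report.json` (machine-readable; model objects stripped) and
#' `report.md` (human-readable summary tables) into `dir`.
#'
#' @param report A `study_report`.
#' @param dir Output directory.
#' @return Paths of the two files, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sanitize <- function(x) {
    if (inherits(x, "glmm_fit")) {
      x <- x[c("fixed", "random", "log_likelihood", "n_parameters",
               "converged", "n_obs", "family")]
    }
    if (inherits(x, "nmds_ordination")) {
      x <- x[c("stress", "k", "converged", "n_restarts")]
    }
    if (inherits(x, "season_comparison")) {
      x <- x[c("rank_sum_statistic", "p_value", "exact")]
    }
    if (inherits(x, "pair_null_quantiles")) return(NULL)
    if (is.list(x) && !is.data.frame(x)) {
      x <- lapply(x, sanitize)
      x <- x[!vapply(x, is.null, logical(1))]
    }
    x
  }
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(sanitize(unclass(report)), json_path,
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows", na = "null")
  md_path <- file.path(dir, "report.md")
  con <- file(md_path, "w")
  on.exit(close(con))
  for (nm in names(report)) {
    cat("## ", nm, " (", report[[nm]]$status, ")\n\n", sep = "", file = con)
    if (!identical(report[[nm]]$status, "ok")) {
      cat(report[[nm]]$reason, "\n\n", file = con)
      next
    }
    for (el in names(report[[nm]])) {
      x <- report[[nm]][[el]]
      if (is.data.frame(x) && nrow(x) <= 40) {
        cat("### ", el, "\n\n", sep = "", file = con)
        write.table(format(x, digits = 4), con, sep = "\t",
                    row.names = FALSE, quote = FALSE)
        cat("\n", file = con)
      } else if (is.numeric(x) && length(x) <= 8) {
        cat("- ", el, ": ", paste(signif(x, 4), collapse = ", "), "\n",
            sep = "", file = con)
      }
    }
    cat("\n", file = con)
  }
  invisible(c(json = json_path, md = md_path))
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report with stages:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, x[[nm]]$status))
  invisible(x)
}
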