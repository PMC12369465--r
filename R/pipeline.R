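# End-to-end orchestration: simulate -> (extract) -> associate ->
# discriminate -> report, with provenance and a run log.

#' Pipeline configuration
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Root seed for every stage.
#' @param cohort A [cohort_spec()]; its seed is overridden by `seed`.
#' @param stages Character subset of
#'   `c("simulate", "extract", "associate", "discriminate", "report")`.
#'   `extract` replaces the archetype feature table with features
#'   extracted from simulated raw traces.
#' @param n_mc Permutations for the association stage.
#' @param n_boot Bootstrap iterations for the KS stage (0 = none).
#' @param alpha FDR / significance level.
#' @param n_bins Histogram bins; `NULL` = Rice rule on the smallest class.
#' @param ks_features Features to run the KS stage on; `NULL` = all.
#' @param trace A [trace_spec()] for the extract stage.
#' @return An object of class `run_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("ctgtime_run_"),
                            seed = 1L,
                            cohort = cohort_spec(),
                            stages = c("simulate", "associate",
                                       "discriminate", "report"),
                            n_mc = 5000L, n_boot = 0L, alpha = 0.05,
                            n_bins = NULL, ks_features = NULL,
                            trace = trace_spec()) {
  bad <- setdiff(stages, c("simulate", "extract", "associate",
                           "discriminate", "report"))
  if (length(bad)) abort(paste0("Unknown stage(s): ", paste(bad, collapse = ", ")))
  cohort$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 cohort = cohort, stages = stages, n_mc = n_mc,
                 n_boot = n_boot, alpha = alpha, n_bins = n_bins,
                 ks_features = ks_features, trace = trace),
            class = "run_config")
}

config_as_list <- function(config) {
  list(seed = config$seed, stages = config$stages, n_mc = config$n_mc,
       n_boot = config$n_boot, alpha = config$alpha,
       n_bins = config$n_bins %||% "rice",
       cohort = list(counts = as.list(config$cohort$counts),
                     n_hospitals = config$cohort$n_hospitals,
                     epochs = length(config$cohort$epoch_grid),
                     archetypes = names(config$cohort$archetypes)))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order and writes a report bundle to
#' `config$out_dir`: `features.csv`, `availability.csv`,
#' `association.csv`, `feature_types.csv`, `ks.csv`, `summary_*.csv`,
#' `binning.json`, `config.yaml` and `run.log`. Identical configurations
#' (including the seed) produce byte-identical CSVs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results
#'   (`features`, `association`, `ks`, `summary`, `paths`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  if ("associate" %in% config$stages && config$n_mc < 1L) {
    abort("Association stage requires n_mc >= 1.")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character()
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  say("ctgtime pipeline; seed %d; stages: %s", config$seed,
      paste(config$stages, collapse = ", "))
  say("alpha %.3g; n_mc %d; n_boot %d; n_bins %s", config$alpha,
      config$n_mc, config$n_boot,
      if (is.null(config$n_bins)) "rice-rule" else as.character(config$n_bins))

  out <- list(paths = character())
  emit <- function(obj, file) {
    p <- file.path(config$out_dir, file)
    readr::write_csv(obj, p)
    out$paths <<- c(out$paths, p)
    p
  }

  tbl <- NULL
  if ("simulate" %in% config$stages) {
    tbl <- generate_feature_table(config$cohort)
    say("simulate: %d rows, %d infants, %d features", nrow(tbl),
        dplyr::n_distinct(tbl$infant_id),
        length(config$cohort$archetypes))
    emit(tbl, "features.csv")
    emit(summarize_availability(tbl), "availability.csv")
  }
  if ("extract" %in% config$stages) {
    cohort <- generate_signal_cohort(config$cohort, config$trace)
    tbl <- extract_cohort_features(cohort)
    say("extract: %d rows from %d traces", nrow(tbl), length(cohort$traces))
    emit(tbl, "features.csv")
    emit(summarize_availability(tbl), "availability.csv")
  }
  if (is.null(tbl) && any(c("associate", "discriminate") %in% config$stages)) {
    abort("Stage 'associate'/'discriminate' needs a feature table: enable 'simulate' or 'extract'.")
  }

  assoc <- NULL
  if ("associate" %in% config$stages) {
    assoc <- ctg_association(tbl, n_mc = config$n_mc, alpha = config$alpha,
                             n_bins = config$n_bins,
                             seed = derive_seed(config$seed, 7L))
    say("associate: %d tests, n_bins %d, %d rejections", assoc$n_tests,
        assoc$n_bins, sum(assoc$results$reject))
    emit(assoc$results, "association.csv")
    emit(assoc$types, "feature_types.csv")
    binning_to_json(assoc$schemes, file.path(config$out_dir, "binning.json"))
  }

  ks <- NULL
  if ("discriminate" %in% config$stages) {
    feats <- config$ks_features %||% setdiff(names(tbl), ID_COLS)
    ks <- purrr::map_dfr(feats, function(f) {
      dplyr::mutate(
        time_resolved_ks(tbl, f, n_boot = config$n_boot,
                         alpha = config$alpha,
                         seed = derive_seed(config$seed, 11L)),
        feature = f, .before = 1)
    })
    say("discriminate: %d features x %d scopes", length(feats),
        length(unique(ks$scope)))
    emit(ks, "ks.csv")
  }

  summ <- NULL
  if ("report" %in% config$stages && !is.null(assoc)) {
    summ <- summarize_associations(assoc)
    emit(summ$kinds, "summary_kinds.csv")
    emit(summ$types, "summary_types.csv")
    say("report: %d significant feature-kind pairs",
        sum(summ$kinds$n_significant))
  }

  yaml::write_yaml(config_as_list(config),
                   file.path(config$out_dir, "config.yaml"))
  writeLines(log_lines, log_path)
  invisible(list(features = tbl, association = assoc, ks = ks,
                 summary = summ, paths = out$paths))
}

#' Summarise an association analysis
#'
#' Counts of significant features per association kind (and per event
#' type, parsed from `bl_`/`ac_`/`dc_`/`ct_` feature-name prefixes where
#' present), plus the feature-taxonomy tally.
#'
#' @param assoc A [ctg_association()] result.
#' @return List of two tibbles: `kinds` and `types`.
#' @export
summarize_associations <- function(assoc) {
  stopifnot(inherits(assoc, "ctg_assoc"))
  res <- assoc$results
  res$event <- dplyr::case_match(substr(res$feature, 1, 3),
                                 "bl_" ~ "baseline", "ac_" ~ "acceleration",
                                 "dc_" ~ "deceleration", "ct_" ~ "contraction",
                                 .default = "other")
  kinds <- dplyr::summarise(
    dplyr::group_by(res, .data$kind, .data$event),
    n_features = dplyr::n(), n_significant = sum(.data$reject),
    .groups = "drop")
  types <- dplyr::count(assoc$types, .data$label, name = "n_features")
  list(kinds = kinds, types = types)
}
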