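
#' Pipeline configuration
#'
#' Run configuration for [run_pipeline()]. The input is either a synthetic
#' run (the generator writes FAERS-dialect quarters first) or a directory
#' of existing FAERS-style quarterly files.
#'
#' @param quarters_dir directory of quarterly files; \code{NULL} for a
#'   synthetic run (the default), in which case the generator writes into
#'   \code{<outdir>/faers/}.
#' @param synthetic a [synthetic_config()] for synthetic runs.
#' @param pt_soc_path TSV path for the PT -> SOC mapping; \code{NULL} uses
#'   the synthetic vocabulary's mapping.
#' @param dictionary a \code{drug_dictionary}.
#' @param curation a [curation_config()].
#' @param criteria a [signal_criteria()].
#' @param comparator_mode \code{"within_class"} (per-agent scans) — the
#'   pooled-class scan and the era sensitivity always use the curated
#'   adult reports as external background.
#' @param cutoff_quarter era split for the sensitivity stage.
#' @param seed integer seed recorded in the manifest and driving all
#'   randomness.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(quarters_dir = NULL,
                            synthetic = synthetic_config(),
                            pt_soc_path = NULL,
                            dictionary = default_drug_dictionary(),
                            curation = curation_config(),
                            criteria = signal_criteria(),
                            comparator_mode = "within_class",
                            cutoff_quarter = "2014Q1",
                            seed = 20240101L) {
  structure(list(quarters_dir = quarters_dir, synthetic = synthetic,
                 pt_soc_path = pt_soc_path, dictionary = dictionary,
                 curation = curation, criteria = criteria,
                 comparator_mode = comparator_mode,
                 cutoff_quarter = cutoff_quarter, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: \code{quarters_dir}, \code{pt_soc_path},
#' \code{cutoff_quarter}, \code{comparator_mode}, \code{seed},
#' \code{criteria} (min_cases, require_ci_low_gt_1, require_chi2_gt,
#' require_ror_gt) and \code{synthetic} (passed to [synthetic_config()]).
#'
#' @param path YAML file.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  crit <- do.call(signal_criteria, as.list(y$criteria))
  syn <- if (is.null(y$synthetic)) synthetic_config() else {
    args <- y$synthetic
    if (!is.null(args$n_cases)) args$n_cases <- unlist(args$n_cases)
    if (!is.null(args$planted)) {
      args$planted <- data.table::rbindlist(args$planted)
    }
    do.call(synthetic_config, args)
  }
  pipeline_config(
    quarters_dir = y$quarters_dir, synthetic = syn,
    pt_soc_path = y$pt_soc_path, criteria = crit,
    comparator_mode = if (is.null(y$comparator_mode)) "within_class" else
      y$comparator_mode,
    cutoff_quarter = if (is.null(y$cutoff_quarter)) "2014Q1" else
      y$cutoff_quarter,
    seed = if (is.null(y$seed)) 20240101L else y$seed)
}

#' Run the surveillance pipeline
#'
#' Orchestrates the stages end to end and writes publication-shaped CSV
#' outputs plus a run manifest. Subcommands: \code{"simulate"} (write
#' synthetic quarters only), \code{"ingest"}, \code{"curate"},
#' \code{"signals"}, \code{"strata"}, \code{"onset"},
#' \code{"sensitivity"}, or \code{"all"}. Later stages imply the earlier
#' ones in-memory; files are only written for the requested stage(s).
#'
#' The manifest records the seed, a hash of the configuration, the
#' attrition chain (raw -> deduplicated -> primary-suspect ->
#' post-PT-filter -> pediatric), the output files with md5 sums and an
#' overall content hash, so a re-run with the same inputs can be verified
#' byte-for-byte (the timestamp is informational and excluded from the
#' hash).
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @param subcommand one stage name or \code{"all"}.
#' @param outdir output directory.
#' @param seed optional override of \code{config$seed}.
#' @return invisibly, a list with the computed objects (\code{cohort},
#'   \code{signals}, ...) and the \code{manifest}.
#' @export
run_pipeline <- function(config = pipeline_config(), subcommand = "all",
                         outdir, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- c("simulate", "ingest", "curate", "signals", "strata", "onset",
              "sensitivity", "all")
  if (!subcommand %in% stages) {
    stop("unknown subcommand '", subcommand, "'; expected one of ",
         paste(stages, collapse = ", "))
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(tab, name) {
    f <- file.path(outdir, name)
    data.table::fwrite(tab, f)
    outputs <<- c(outputs, f)
  }
  want <- function(st) subcommand %in% c(st, "all")
  results <- list()

  # --- simulate / locate input quarters
  quarters_dir <- config$quarters_dir
  synthetic_run <- is.null(quarters_dir)
  if (synthetic_run) {
    quarters_dir <- file.path(outdir, "faers")
    syn <- config$synthetic
    syn$seed <- config$seed
    bundles <- generate_faers(syn)
    write_faers(bundles, quarters_dir)
    emit(attr(bundles, "truth")$planted, "planted_truth.csv")
    if (subcommand == "simulate") {
      manifest <- write_manifest(outdir, config, outputs, attrition = NULL)
      return(invisible(list(bundles = bundles, manifest = manifest)))
    }
  }

  # --- ingest
  bundles <- read_quarters(quarters_dir)
  results$bundles <- bundles
  if (subcommand == "ingest") {
    counts <- data.table::rbindlist(lapply(bundles, function(b) {
      data.table::data.table(quarter = b$quarter_id,
                             table = names(b$tables),
                             rows = vapply(b$tables, nrow, 0L))
    }))
    emit(counts, "ingest_counts.csv")
    manifest <- write_manifest(outdir, config, outputs, attrition = NULL)
    return(invisible(c(results, list(manifest = manifest))))
  }

  # --- curate
  pt_to_soc <- if (!is.null(config$pt_soc_path)) {
    read_pt_soc(config$pt_soc_path)
  } else {
    v <- synthetic_vocabulary()
    stats::setNames(v$soc, v$pt)
  }
  cohort <- curate_cohort(bundles, config$dictionary, config$curation,
                          pt_to_soc)
  results$cohort <- cohort
  if (want("curate")) {
    attr_tab <- data.table::data.table(stage = names(cohort$attrition),
                                       count = as.integer(cohort$attrition))
    emit(attr_tab, "attrition.csv")
  }

  adult_cases <- cohort$all_cases[is.na(age_years) | age_years >= 18]
  background <- background_from_cases(adult_cases)

  # --- signals
  if (want("signals") || want("strata")) {
    signals <- signal_scan(cohort, comparator_mode = config$comparator_mode,
                           criteria = config$criteria)
    class_signals <- signal_scan(cohort, drugs = "class",
                                 comparator_mode = "external_background",
                                 background = background,
                                 criteria = config$criteria)
    results$signals <- signals
    results$class_signals <- class_signals
    if (want("signals")) {
      write_signal_csv(signals, file.path(outdir, "signals_by_drug.csv"))
      outputs <- c(outputs, file.path(outdir, "signals_by_drug.csv"))
      write_signal_csv(class_signals, file.path(outdir, "signals_class.csv"))
      outputs <- c(outputs, file.path(outdir, "signals_class.csv"))
      rsr_tab <- signals[, list(n_pts = .N, n_signals = sum(is_signal)),
                         by = drug]
      rsr_tab[, rsr_pct := rsr(n_signals, n_pts)]
      emit(rsr_tab, "rsr_by_drug.csv")
      emit(prioritize(signals), "signal_priority.csv")
      emit(soc_aggregate(signals), "soc_signals.csv")
    }
  }

  # --- strata
  if (want("strata")) {
    emit(demographics_table(cohort$cases), "demographics.csv")
    sc <- stratum_compare(cohort$cases)
    emit(sc$soc, "stratum_soc.csv")
    emit(sc$top_pts, "stratum_top10.csv")
  }

  # --- onset
  if (want("onset")) {
    emit(onset_by_agent(cohort), "onset_summary.csv")
    dd <- onset_days(cohort$cases$therapy_start, cohort$cases$event_date)
    emit(onset_summary(dd)$bins, "onset_bins.csv")
  }

  # --- sensitivity
  if (want("sensitivity")) {
    sens <- era_compare(cohort, drug = "class",
                        comparator_mode = "external_background",
                        cutoff_quarter = config$cutoff_quarter)
    results$sensitivity <- sens
    emit(sens$table, "era_comparison.csv")
    w <- sens$wilcoxon
    emit(data.table::data.table(statistic = c("W", "Z", "p", "median_diff",
                                              "n_pairs"),
                                value = c(w$W, w$Z, w$p, w$median_diff,
                                          w$n)),
         "era_wilcoxon.csv")
  }

  manifest <- write_manifest(outdir, config, outputs,
                             attrition = cohort$attrition)
  invisible(c(results, list(manifest = manifest)))
}

# manifest: config hash, seed, attrition chain, outputs with md5s and an
# overall content hash (order-independent); timestamp informational only
write_manifest <- function(outdir, config, outputs, attrition) {
  cfg_repr <- utils::capture.output(utils::str(
    config[setdiff(names(config), "dictionary")]))
  cfg_hash <- md5_of_lines(cfg_repr)
  files <- sort(unique(outputs))
  md5 <- if (length(files)) unname(tools::md5sum(files)) else character(0)
  content_hash <- md5_of_lines(paste(basename(files), md5))
  manifest <- list(
    seed = config$seed,
    config_hash = unname(cfg_hash),
    attrition = as.list(attrition),
    outputs = stats::setNames(as.list(md5), basename(files)),
    content_hash = unname(content_hash),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

# hash helper: md5sum works on files, so round-trip through a temp file
md5_of_lines <- function(lines) {
  f <- tempfile(fileext = ".hash")
  on.exit(unlink(f))
  writeLines(lines, f)
  unname(tools::md5sum(f))
}
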