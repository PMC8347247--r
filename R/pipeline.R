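# Pipeline commands: simulate -> prepare -> run, driven by one validated
# configuration. Each command logs its config hash, seeds and per-stage row
# counts, so any reported number can be re-derived from the logs.

#' Pipeline configuration
#'
#' Central configuration for the three pipeline commands. All defaults can be
#' overridden here or from a YAML file via [read_pipeline_config()]; unknown
#' keys are rejected.
#'
#' @param cohort_csv Path of the cohort exam CSV ([cmd_simulate()] writes it,
#'   the other commands read it).
#' @param out_dir Output directory for triplet tables, metrics and model
#'   archives.
#' @param cohort Named list of [cohort_spec()] arguments for
#'   [cmd_simulate()].
#' @param sw Named vector of within-subject SDs (see
#'   [compute_repeatability()]); alternatively supply `r_values` with the
#'   repeatability limits directly.
#' @param r_values Optional named vector of repeatability limits; takes
#'   precedence over `sw`.
#' @param severity_threshold Baseline `LOGIK` exclusion threshold.
#' @param opposing_factor,inside_factor Noise-reduction shrink factors.
#' @param option Quality policy: `"OPTION1"`, `"OPTION2"` or `"BOTH"` (run
#'   both and compare them with a Wilcoxon test).
#' @param training Named list of [training_config()] arguments.
#' @param n_iterations Retrain iterations for [cmd_run()] (default 10).
#' @param base_seed Base seed for simulation and the retrain protocol.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_csv = "cohort.csv",
                            out_dir = ".",
                            cohort = list(n_eyes = 200L),
                            sw = default_sw(),
                            r_values = NULL,
                            severity_threshold = 3.5,
                            opposing_factor = 5,
                            inside_factor = 2,
                            option = "OPTION1",
                            training = list(),
                            n_iterations = 10L,
                            base_seed = 1L) {
  check_that(is.character(cohort_csv) && length(cohort_csv) == 1L,
             "'cohort_csv' must be a single path")
  check_that(option %in% c("OPTION1", "OPTION2", "BOTH"),
             "'option' must be OPTION1, OPTION2 or BOTH")
  check_that(is_count(n_iterations, 1L),
             "'n_iterations' must be a positive integer")
  check_that(is_count(base_seed) || is_count(-base_seed),
             "'base_seed' must be an integer")
  check_that(is.list(cohort), "'cohort' must be a named list of cohort_spec args")
  check_that(is.list(training),
             "'training' must be a named list of training_config args")
  bad <- setdiff(names(cohort), names(formals(cohort_spec)))
  check_that(length(bad) == 0L, "unknown cohort key(s): %s",
             paste(bad, collapse = ", "))
  bad <- setdiff(names(training), names(formals(training_config)))
  check_that(length(bad) == 0L, "unknown training key(s): %s",
             paste(bad, collapse = ", "))
  rt <- if (!is.null(r_values)) repeatability_from_r(unlist(r_values)) else
    compute_repeatability(unlist(sw))
  structure(
    list(cohort_csv = cohort_csv, out_dir = out_dir, cohort = cohort,
         repeatability = rt, severity_threshold = severity_threshold,
         opposing_factor = opposing_factor, inside_factor = inside_factor,
         option = option, training = training,
         n_iterations = as.integer(n_iterations),
         base_seed = as.integer(base_seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Precedence: `overrides` > file > [pipeline_config()] defaults. Unknown
#' top-level keys are rejected.
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @param overrides Named list applied on top of the file values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  check_that(file.exists(path), "config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  check_that(length(bad) == 0L, "unknown config key(s): %s",
             paste(bad, collapse = ", "))
  for (nm in c("sw", "r_values")) {
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  }
  do.call(pipeline_config, vals)
}

# Short stable hash of the config for the logs (polynomial rolling hash over
# the serialized object; stays below 2^53 so double arithmetic is exact).
config_hash <- function(config) {
  bytes <- as.integer(serialize(unclass(config), NULL, version = 2))
  hash <- 5381
  for (b in bytes) hash <- (hash * 31 + b) %% 2147483647
  sprintf("%08x", hash)
}

log_msg <- function(fmt, ...) message(sprintf(paste0("[keraprog] ", fmt), ...))

#' Simulate a cohort and write it to disk
#'
#' Wraps [generate_cohort()]: writes the exam table to `cohort_csv` and the
#' eye-level ground truth to a sibling `*_truth.csv`.
#'
#' @param config A [pipeline_config()]; `config$cohort` supplies the
#'   [cohort_spec()] arguments (its seed defaults to `base_seed`).
#' @return The `kc_cohort`, invisibly.
#' @export
cmd_simulate <- function(config) {
  check_that(inherits(config, "pipeline_config"),
             "'config' must be a pipeline_config")
  args <- config$cohort
  if (is.null(args$seed)) args$seed <- config$base_seed
  spec <- do.call(cohort_spec, args)
  cohort <- generate_cohort(spec)
  dir.create(dirname(config$cohort_csv), recursive = TRUE, showWarnings = FALSE)
  write_cohort(cohort, config$cohort_csv)
  truth_path <- sub("\\.csv$", "_truth.csv", config$cohort_csv)
  utils::write.csv(cohort$truth, truth_path, row.names = FALSE, quote = FALSE)
  log_msg("simulate: config %s, seed %d", config_hash(config), spec$seed)
  log_msg("simulate: %d eyes, %d exams -> %s (truth: %s)",
          nrow(cohort$truth), nrow(cohort$exams), config$cohort_csv, truth_path)
  invisible(cohort)
}

#' Preprocess a cohort into labelled triplets
#'
#' Runs build -> quality filter -> severity filter -> label -> noise-reduce
#' for the configured quality option, logging the count surviving each stage,
#' and writes the triplet table plus a JSON label summary (stable/suspect
#' counts and the histogram of how many variables exceeded their limit).
#'
#' @param config A [pipeline_config()].
#' @param option Quality policy; defaults to `config$option` (`"BOTH"` is
#'   resolved per call, so pass `"OPTION1"` or `"OPTION2"` explicitly here).
#' @return The prepared `kc_triplets`, invisibly.
#' @export
cmd_prepare <- function(config, option = NULL) {
  check_that(inherits(config, "pipeline_config"),
             "'config' must be a pipeline_config")
  if (is.null(option)) option <- config$option
  check_that(option %in% c("OPTION1", "OPTION2"),
             "prepare needs a single option (OPTION1 or OPTION2)")
  exams <- read_cohort(config$cohort_csv)
  tr <- build_triplets(exams)
  funnel <- c(exams = nrow(exams), built = nrow(tr))
  tr <- filter_quality(tr, option)
  funnel["quality"] <- nrow(tr)
  tr <- filter_severity(tr, config$severity_threshold)
  funnel["severity"] <- nrow(tr)
  tr <- label_progression(tr, config$repeatability)
  tr <- noise_reduce(tr, config$repeatability,
                     config$opposing_factor, config$inside_factor)
  attr(tr, "funnel") <- funnel

  log_msg("prepare[%s]: config %s", option, config_hash(config))
  log_msg("prepare[%s]: exams %d -> triplets %d -> quality %d -> severity %d",
          option, funnel["exams"], funnel["built"], funnel["quality"],
          funnel["severity"])
  n_suspect <- sum(tr$label == "SUSPECT_PROGRESSIVE")
  log_msg("prepare[%s]: %d stable, %d suspect progressive",
          option, nrow(tr) - n_suspect, n_suspect)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out_csv <- file.path(config$out_dir, sprintf("triplets_%s.csv",
                                               tolower(option)))
  write_tr <- tr
  for (slot in TRIPLET_SLOTS) {
    col <- paste0("date_", slot)
    write_tr[[col]] <- format(write_tr[[col]], "%Y-%m-%d")
  }
  utils::write.csv(write_tr, out_csv, row.names = FALSE, quote = FALSE)

  summary <- list(
    option = option,
    funnel = as.list(funnel),
    n_stable = nrow(tr) - n_suspect,
    n_suspect_progressive = n_suspect,
    exceedance_histogram = as.list(stats::setNames(
      vapply(1:5, function(k) sum(tr$n_exceed == k), integer(1)),
      paste0("n", 1:5)))
  )
  jsonlite::write_json(summary, file.path(config$out_dir,
                                          sprintf("labels_%s.json",
                                                  tolower(option))),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(tr)
}

#' Run the retrain protocol end to end
#'
#' Prepares the triplets for the configured option(s), runs [run_protocol()],
#' and writes: a metrics CSV in the standard report layout (rows SENS, SPEC,
#' PPV, NPV; one column per iteration plus AVG, percentages rounded to one
#' decimal), a Bland-Altman summary CSV over all holdout forecasts, a JSON
#' run summary with the raw unrounded values, and (optionally) per-iteration
#' model archives. With `option = "BOTH"` both policies are run and compared
#' with [compare_options_wilcoxon()].
#'
#' @param config A [pipeline_config()].
#' @param store_models Write each iteration's trained model as JSON.
#' @return Invisibly, a list with one `kc_protocol` per option and, for
#'   `"BOTH"`, the Wilcoxon comparison.
#' @export
cmd_run <- function(config, store_models = FALSE) {
  check_that(inherits(config, "pipeline_config"),
             "'config' must be a pipeline_config")
  options <- if (config$option == "BOTH") c("OPTION1", "OPTION2") else
    config$option
  tcfg <- do.call(training_config, config$training)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- list()
  for (opt in options) {
    tr <- cmd_prepare(config, option = opt)
    log_msg("run[%s]: %d triplets, %d iterations, base seed %d",
            opt, nrow(tr), config$n_iterations, config$base_seed)
    prot <- run_protocol(tr, config$repeatability, tcfg,
                         n_iterations = config$n_iterations,
                         base_seed = config$base_seed,
                         store_models = store_models)
    results[[opt]] <- prot

    tag <- tolower(opt)
    utils::write.csv(metrics_report_table(prot),
                     file.path(config$out_dir, sprintf("metrics_%s.csv", tag)),
                     row.names = FALSE, quote = FALSE)
    ba <- bland_altman(
      as.matrix(stats::setNames(
        prot$predictions[paste0("interpolated_", KC_VARIABLES)], KC_VARIABLES)),
      as.matrix(stats::setNames(
        prot$predictions[paste0("measured_", KC_VARIABLES)], KC_VARIABLES)),
      config$repeatability)
    utils::write.csv(as.data.frame(ba),
                     file.path(config$out_dir,
                               sprintf("bland_altman_%s.csv", tag)),
                     row.names = FALSE, quote = FALSE)
    if (store_models) {
      for (i in seq_along(prot$models)) {
        save_tdnn(prot$models[[i]],
                  file.path(config$out_dir,
                            sprintf("model_%s_iter%02d.json", tag, i)))
      }
    }
    log_msg("run[%s]: mean sens %.1f%%, spec %.1f%%, ppv %.1f%%, npv %.1f%%",
            opt, prot$mean["sensitivity"], prot$mean["specificity"],
            prot$mean["ppv"], prot$mean["npv"])
  }

  summary <- list(config_hash = config_hash(config),
                  base_seed = config$base_seed,
                  n_iterations = config$n_iterations)
  for (opt in options) {
    summary[[opt]] <- list(metrics = results[[opt]]$metrics,
                           mean = as.list(results[[opt]]$mean))
  }
  if (length(options) == 2L) {
    comparison <- compare_options_wilcoxon(results$OPTION1, results$OPTION2)
    results$comparison <- comparison
    summary$wilcoxon <- comparison
    utils::write.csv(comparison,
                     file.path(config$out_dir, "wilcoxon_option1_vs_option2.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(summary, file.path(config$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(results)
}

# Table-1-style layout: rows SENS/SPEC/PPV/NPV, iteration columns plus AVG.
metrics_report_table <- function(protocol) {
  m <- protocol$metrics
  rows <- c(sensitivity = "SENS", specificity = "SPEC", ppv = "PPV",
            npv = "NPV")
  out <- data.frame(metric = unname(rows), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(m))) {
    out[[paste0("iter", i)]] <- round(unlist(m[i, names(rows)]), 1)
  }
  out$AVG <- round(unname(protocol$mean[names(rows)]), 1)
  out
}
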