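#' Pipeline run configuration
#'
#' Gathers every knob of an end-to-end run: input paths (or a simulated
#' cohort), the window and coverage settings, the augmentation grid, the
#' model hyperparameters, the decision threshold and the seed. The config
#' is fully serializable to YAML; its hash is embedded in every output so
#' a report can always be traced to the exact settings that produced it.
#'
#' @param tft_path,sleep_path Input CSV/JSON paths (`sleep_path` may be a
#'   per-sample CSV or a pre-aggregated JSON, decided by extension).
#'   Leave `NULL` with `simulate = TRUE` to run on a synthetic cohort.
#' @param simulate Use [generate_cohort()] instead of reading inputs.
#' @param cohort A [cohort_config()] used when `simulate` is `TRUE`.
#' @param n_days Window length, days.
#' @param include_anchor_morning Window convention, see [extract_window()].
#' @param min_nights,min_samples Coverage rule, see [coverage_rule()].
#' @param step_days Augmentation grid, see [augment_dataset()].
#' @param tsh_floor Quotient-feature clamp, see [featurize()].
#' @param model A [model_config()].
#' @param threshold Decision threshold on the averaged probability.
#' @param seed Integer seed for model fits.
#' @param out_dir Output directory for [run_pipeline()] artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(tft_path = NULL, sleep_path = NULL,
                       simulate = is.null(tft_path),
                       cohort = cohort_config(),
                       n_days = 10L, include_anchor_morning = FALSE,
                       min_nights = 3L, min_samples = 300L,
                       step_days = 7L, tsh_floor = 0.025,
                       model = model_config(), threshold = 0.5,
                       seed = 1L, out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

#' @rdname run_config
#' @param path A YAML file with (a subset of) the fields of `run_config`;
#'   nested `cohort:` and `model:` blocks override those configs' defaults.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- do.call(cohort_config, y$cohort %||% list())
  model <- do.call(model_config, y$model %||% list())
  y$cohort <- NULL
  y$model <- NULL
  do.call(run_config, c(y, list(cohort = cohort, model = model)))
}

## Hash of the settings that determine results; where outputs land is not
## part of a run's identity.
config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  rlang::hash(x)
}

load_inputs <- function(config) {
  if (isTRUE(config$simulate)) {
    cohort <- generate_cohort(config$cohort)
    return(list(tft = cohort$tft, nights = cohort$nights, truth = cohort$truth))
  }
  nights <- if (grepl("\\.json$", config$sleep_path, ignore.case = TRUE)) {
    read_sleep_json(config$sleep_path)
  } else {
    read_sleep_csv(config$sleep_path)
  }
  list(tft = read_tft_csv(config$tft_path), nights = nights, truth = NULL)
}

#' Run the full prediction pipeline
#'
#' Executes ingest (or simulation) -> pair construction -> interpolation
#' augmentation -> modified LOOCV -> metrics and feature importance, and,
#' when `config$out_dir` is set, writes `predictions.csv`,
#' `confusion_full.csv`, `confusion_excluding_subclinical.csv`,
#' `metrics.json`, `importance.csv` and `run_log.txt` (seed, config hash,
#' per-stage record counts). Identical configs give identical outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return A list of class `pipeline_report` with the dataset, predictions,
#'   both confusion matrices, both metric reports, the importance report
#'   and the per-stage counts.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  say <- function(...) if (!quiet) inform(sprintf(...))

  inputs <- load_inputs(config)
  say("ingest: %d TFTs, %d nights", nrow(inputs$tft), nrow(inputs$nights))

  coverage <- coverage_rule(config$min_nights, config$min_samples)
  ds <- build_dataset(inputs$tft, inputs$nights, n_days = config$n_days,
                      coverage = coverage, tsh_floor = config$tsh_floor,
                      include_anchor_morning = config$include_anchor_morning)
  n_obs_cases <- nrow(ds$cases)
  say("pairs: %d observed (%d usable), %d observed cases",
      sum(ds$pairs$origin == "observed"), sum(ds$pairs$usable), n_obs_cases)

  ds <- augment_dataset(ds, step_days = config$step_days)
  say("augment: %d pairs, %d cases", nrow(ds$pairs), nrow(ds$cases))

  preds <- loocv_predict(ds, config = config$model,
                         threshold = config$threshold, seed = config$seed,
                         collect_importance = TRUE)
  say("loocv: %d targets evaluated, %d skipped", nrow(preds),
      attr(preds, "n_skipped"))

  cm_full <- confusion(preds)
  cm_excl <- confusion(preds, exclude_subclinical = TRUE)
  report <- structure(
    list(config = config, config_hash = hash, dataset = ds,
         predictions = preds,
         confusion_full = cm_full, confusion_excl = cm_excl,
         metrics_full = metrics(cm_full), metrics_excl = metrics(cm_excl),
         importance = attr(preds, "importance"),
         counts = list(tfts = nrow(inputs$tft), nights = nrow(inputs$nights),
                       pairs = nrow(ds$pairs), observed_cases = n_obs_cases,
                       augmented_cases = nrow(ds$cases),
                       targets = nrow(preds))),
    class = "pipeline_report")

  if (!is.null(config$out_dir)) write_pipeline_report(report, config$out_dir)
  report
}

metric_report_json <- function(m) {
  list(sensitivity = m$sensitivity, specificity = m$specificity,
       ppv = m$ppv, npv = m$npv,
       tp = m$cm$tp, fn = m$cm$fn, fp = m$cm$fp, tn = m$cm$tn)
}

write_pipeline_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  preds <- report$predictions
  preds_flat <- preds[setdiff(names(preds), "referred_probs")]
  readr::write_csv(preds_flat, file.path(dir, "predictions.csv"))
  cm_row <- function(cm) tibble::tibble(tp = cm$tp, fn = cm$fn,
                                        fp = cm$fp, tn = cm$tn)
  readr::write_csv(cm_row(report$confusion_full),
                   file.path(dir, "confusion_full.csv"))
  readr::write_csv(cm_row(report$confusion_excl),
                   file.path(dir, "confusion_excluding_subclinical.csv"))
  jsonlite::write_json(
    list(config_hash = report$config_hash, seed = report$config$seed,
         full = metric_report_json(report$metrics_full),
         excluding_subclinical = metric_report_json(report$metrics_excl)),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(report$importance)) {
    write_importance_csv(report$importance, file.path(dir, "importance.csv"))
  }
  log_lines <- c(
    sprintf("config_hash: %s", report$config_hash),
    sprintf("seed: %d", report$config$seed),
    sprintf("threshold: %g", report$config$threshold),
    sprintf("n_days: %d", report$config$n_days),
    vapply(names(report$counts),
           function(nm) sprintf("%s: %d", nm, report$counts[[nm]]),
           character(1))
  )
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> config %s\n", x$config_hash))
  cat("full cohort:            "); print(x$metrics_full)
  cat("excluding subclinical:  "); print(x$metrics_excl)
  invisible(x)
}
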