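#' Configuration of the synthetic wearable cohort
#'
#' Describes a cohort of treated thyroid-dysfunction patients monitored
#' with a wrist wearable: 3 or 4 thyroid function tests per patient at
#' >= 4-week intervals, and nightly sleep heart-rate series whose mean is
#' coupled to the same-day latent free T4. Three patient groups are
#' generated. Thyrotoxic patients start above the free T4 reference range
#' and decay exponentially toward the euthyroid midpoint under treatment;
#' hypothyroid patients start below it and recover toward the midpoint;
#' euthyroid patients are stable. Latent TSH responds log-linearly to the
#' free T4 deviation with a physiological lag (the pituitary recovers
#' weeks after free T4 normalises, which is what produces the large
#' subclinical-thyrotoxicosis fraction seen in treated cohorts), saturating
#' at the assay floor of 0.025 mIU/L.
#'
#' The default heart-rate coupling slope of 22 bpm per ng/dL corresponds
#' to 11 bpm per 0.5 ng/dL, the association size reported for resting
#' sleep heart rate in thyrotoxic patients; it is a tunable default, not a
#' claim. Night-level jitter models day-to-day resting-HR variability on
#' top of within-night sample noise.
#'
#' @param n_patients Number of patients.
#' @param tft_counts Named probability vector over the number of TFTs per
#'   patient (default 38/175 with 3 and 137/175 with 4). Counts are
#'   allocated deterministically in these proportions (up to rounding) and
#'   shuffled across patients, so the default 175-patient cohort has
#'   exactly 38 patients with 3 tests and 137 with 4, i.e. 662 pairs.
#' @param inter_tft_gap Minimum gap between consecutive TFTs, days.
#' @param gap_jitter Uniform 0..`gap_jitter` extra days added to each gap.
#' @param group_probs Named probabilities for patient groups
#'   `thyrotoxic`, `euthyroid`, `hypothyroid`.
#' @param ft4_mid Euthyroid midpoint free T4, ng/dL.
#' @param thyro_ft4_excess Lognormal (meanlog, sdlog) of the initial free
#'   T4 excess above the upper limit in the thyrotoxic group.
#' @param thyro_decay Range of the exponential decay rate (per day) toward
#'   the midpoint under treatment, thyrotoxic group.
#' @param hypo_ft4_init Uniform range of initial free T4 in the
#'   hypothyroid group, ng/dL.
#' @param hypo_recovery Range of the recovery rate (per day), hypothyroid
#'   group.
#' @param eu_ft4 Mean and SD of stable euthyroid free T4, ng/dL.
#' @param tsh_setpoint TSH (mIU/L) at the euthyroid reference free T4 1.22
#'   ng/dL.
#' @param tsh_slope Decades of TSH per ng/dL of free T4 deviation.
#' @param tsh_lag Lag of the TSH response behind free T4, days.
#' @param tsh_floor,tsh_cap Saturation bounds of latent TSH, mIU/L.
#' @param tsh_person_sd SD (log10 units) of the per-patient TSH setpoint.
#' @param hr_baseline Mean and SD (across patients) of baseline sleeping
#'   HR, bpm.
#' @param hr_coupling_slope Added bpm of nightly mean HR per ng/dL of
#'   same-day free T4 above `ft4_mid`.
#' @param hr_night_jitter SD of the night-level mean-HR deviation, bpm.
#' @param hr_night_noise Within-night sample SD, bpm.
#' @param night_length Mean and SD of samples per night.
#' @param min_night_length Lower clamp on samples per night.
#' @param missing_night_prob Probability a night is absent entirely.
#' @param ft4_assay_sd SD of assay noise on reported free T4, ng/dL.
#' @param tsh_assay_cv Coefficient of variation of assay noise on TSH.
#' @param start_date First possible monitoring date.
#' @param seed Integer seed; generation is reproducible given the config.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 175L,
                          tft_counts = c(`3` = 38, `4` = 137) / 175,
                          inter_tft_gap = 28L,
                          gap_jitter = 7L,
                          group_probs = c(thyrotoxic = 0.73,
                                          euthyroid = 0.155,
                                          hypothyroid = 0.115),
                          ft4_mid = 1.335,
                          thyro_ft4_excess = c(meanlog = log(0.7), sdlog = 0.55),
                          thyro_decay = c(0.018, 0.045),
                          hypo_ft4_init = c(0.45, 0.85),
                          hypo_recovery = c(0.0025, 0.008),
                          eu_ft4 = c(mean = 1.22, sd = 0.12),
                          tsh_setpoint = 1.45,
                          tsh_slope = 1.8,
                          tsh_lag = 45L,
                          tsh_floor = 0.025,
                          tsh_cap = 60,
                          tsh_person_sd = 0.25,
                          hr_baseline = c(mean = 62, sd = 5),
                          hr_coupling_slope = 22,
                          hr_night_jitter = 3,
                          hr_night_noise = 5,
                          night_length = c(mean = 400, sd = 60),
                          min_night_length = 60L,
                          missing_night_prob = 0.1,
                          ft4_assay_sd = 0.03,
                          tsh_assay_cv = 0.05,
                          start_date = as.Date("2023-03-01"),
                          seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_patients < 1) abort("n_patients must be >= 1")
  if (abs(sum(cfg$tft_counts) - 1) > 1e-9) {
    cfg$tft_counts <- cfg$tft_counts / sum(cfg$tft_counts)
  }
  if (abs(sum(cfg$group_probs) - 1) > 1e-9) {
    abort("group_probs must sum to 1")
  }
  if (cfg$missing_night_prob < 0 || cfg$missing_night_prob > 1) {
    abort("missing_night_prob must be in [0, 1]")
  }
  positive <- c("inter_tft_gap", "tsh_slope", "tsh_floor", "tsh_cap",
                "hr_night_noise", "tsh_setpoint")
  for (nm in positive) {
    if (any(cfg[[nm]] <= 0)) abort(paste0(nm, " must be positive"))
  }
  if (cfg$hr_coupling_slope < 0) abort("hr_coupling_slope must be >= 0")
  structure(cfg, class = "cohort_config")
}

## Latent free T4 at integer day offsets (0 = monitoring start) for one
## patient; exponential approach toward the euthyroid midpoint.
latent_ft4_fun <- function(group, f0, rate, ft4_mid) {
  force(group); force(f0); force(rate); force(ft4_mid)
  function(day) ft4_mid + (f0 - ft4_mid) * exp(-rate * day)
}

#' Generate a synthetic cohort
#'
#' Draws patients, their latent free T4 / TSH trajectories, visit-day TFT
#' results (latent value plus assay noise) and nightly sleep heart-rate
#' series (baseline + coupling x free T4 deviation + night jitter, with
#' integer-bpm samples). Nights follow the sleep-ends-on-date convention
#' and cover the 10 days before the first test through the last test, with
#' nights missing independently at `missing_night_prob`. A truth table
#' records the latent values and state at every visit for
#' parameter-recovery tests.
#'
#' @param config A [cohort_config()].
#' @param hr Generate sleep nights? `FALSE` returns TFTs and truth only
#'   (fast path for class-mix studies).
#' @return An object of class `synthetic_cohort`: list with `tft`,
#'   `nights`, `truth` tibbles and the `config`.
#' @export
generate_cohort <- function(config = cohort_config(), hr = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%04d", seq_len(n))
  groups <- sample(names(config$group_probs), n, replace = TRUE,
                   prob = config$group_probs)
  ## deterministic allocation of visit counts (the configured proportions
  ## hold exactly, up to rounding), randomly assigned across patients
  ks <- as.integer(names(config$tft_counts))
  alloc <- diff(c(0, round(cumsum(config$tft_counts * n))))
  k_tft <- sample(rep(ks, alloc))
  upper <- config$ft4_mid + (1.78 - 0.89) / 2 # 1.78 at default mid

  tft_rows <- vector("list", n)
  truth_rows <- vector("list", n)
  night_rows <- if (hr) vector("list", n) else NULL

  for (i in seq_len(n)) {
    g <- groups[i]
    if (g == "thyrotoxic") {
      f0 <- upper + rlnorm(1, config$thyro_ft4_excess[["meanlog"]],
                           config$thyro_ft4_excess[["sdlog"]])
      rate <- runif(1, config$thyro_decay[1], config$thyro_decay[2])
    } else if (g == "hypothyroid") {
      f0 <- runif(1, config$hypo_ft4_init[1], config$hypo_ft4_init[2])
      rate <- runif(1, config$hypo_recovery[1], config$hypo_recovery[2])
    } else {
      f0 <- min(max(rnorm(1, config$eu_ft4[["mean"]], config$eu_ft4[["sd"]]),
                    0.95), 1.70)
      rate <- 0
    }
    ft4_at <- latent_ft4_fun(g, f0, rate, config$ft4_mid)
    tsh_shift <- rnorm(1, 0, config$tsh_person_sd) # per-patient setpoint
    tsh_at <- function(day) {
      f_lag <- ft4_at(day - config$tsh_lag)
      lt <- log10(config$tsh_setpoint) - config$tsh_slope * (f_lag - 1.22) +
        tsh_shift
      min(max(10^lt, config$tsh_floor), config$tsh_cap)
    }

    first_visit <- 10L + sample.int(31L, 1L) - 1L # day of first TFT
    k <- k_tft[i]
    gaps <- config$inter_tft_gap +
      sample.int(config$gap_jitter + 1L, k - 1L, replace = TRUE) - 1L
    visit_days <- first_visit + c(0L, cumsum(gaps))
    visit_dates <- config$start_date + visit_days

    lat_f <- vapply(visit_days, ft4_at, numeric(1))
    lat_t <- vapply(visit_days, tsh_at, numeric(1))
    obs_f <- pmax(round(lat_f + rnorm(k, 0, config$ft4_assay_sd), 2), 0.06)
    obs_t <- pmax(round(lat_t * exp(rnorm(k, 0, config$tsh_assay_cv)), 3),
                  config$tsh_floor)

    tft_rows[[i]] <- tibble::tibble(
      patient_id = ids[i], test_date = visit_dates,
      free_t4 = obs_f, tsh = obs_t)
    truth_rows[[i]] <- tibble::tibble(
      patient_id = ids[i], date = visit_dates,
      latent_ft4 = round(lat_f, 4), latent_tsh = round(lat_t, 4),
      state = as.character(classify_state(pmax(lat_f, 0.06), lat_t)))

    if (hr) {
      baseline <- rnorm(1, config$hr_baseline[["mean"]],
                        config$hr_baseline[["sd"]])
      days <- seq(visit_days[1] - 10L, visit_days[k])
      present <- runif(length(days)) >= config$missing_night_prob
      days <- days[present]
      if (length(days)) {
        lens <- pmax(as.integer(round(rnorm(length(days),
                                            config$night_length[["mean"]],
                                            config$night_length[["sd"]]))),
                     config$min_night_length)
        mus <- baseline +
          config$hr_coupling_slope *
            (vapply(days, ft4_at, numeric(1)) - config$ft4_mid) +
          rnorm(length(days), 0, config$hr_night_jitter)
        samples <- lapply(seq_along(days), function(j) {
          s <- as.integer(round(rnorm(lens[j], mus[j], config$hr_night_noise)))
          pmin(pmax(s, 21L), 249L)
        })
        night_rows[[i]] <- tibble::tibble(
          patient_id = ids[i], date = config$start_date + days,
          samples = samples, n_samples = lens)
      }
    }
  }

  structure(
    list(tft = dplyr::bind_rows(tft_rows),
         nights = if (hr) dplyr::bind_rows(night_rows) else NULL,
         truth = dplyr::bind_rows(truth_rows),
         config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d TFTs, %s nights\n",
              length(unique(x$tft$patient_id)), nrow(x$tft),
              if (is.null(x$nights)) "no" else format(nrow(x$nights))))
  print(round(100 * prop.table(table(x$truth$state)), 1))
  invisible(x)
}

#' Write or read a synthetic cohort as plain-text files
#'
#' Writes `tft.csv` (the TFT-ingestion dialect), `sleep.json` (the
#' pre-aggregated night dialect) and `truth.csv` into `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()`
#'   returns a list with `tft`, `nights` and `truth` tibbles.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$tft, file.path(dir, "tft.csv"))
  if (!is.null(cohort$nights)) {
    write_sleep_json(cohort$nights, file.path(dir, "sleep.json"))
  }
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  nights_path <- file.path(dir, "sleep.json")
  list(
    tft = read_tft_csv(file.path(dir, "tft.csv")),
    nights = if (file.exists(nights_path)) read_sleep_json(nights_path),
    truth = readr::read_csv(file.path(dir, "truth.csv"),
                            show_col_types = FALSE)
  )
}

#' End-to-end recovery check on a synthetic cohort
#'
#' Generates a cohort, runs the full pipeline (pair construction,
#' interpolation augmentation, modified LOOCV) and scores the decisions
#' against the cohort's thyroid function tests. With strong heart-rate
#' coupling the system should recover high sensitivity and specificity;
#' with the coupling slope at zero the heart-rate features carry no signal
#' and the Youden index (sensitivity + specificity - 100) should sit near
#' zero.
#'
#' @param config A [cohort_config()].
#' @param n_days Window length, days.
#' @param step_days Augmentation grid, days.
#' @param model A [model_config()].
#' @param threshold Decision threshold.
#' @param coverage A [coverage_rule()].
#' @param keep_fold_details Passed to [loocv_predict()]; retains per-fold
#'   training keys on the predictions for leakage audits.
#' @return A list of class `recovery_report`: `predictions`, `confusion`,
#'   `metrics`, `youden`, `n_pairs`, `n_cases`, `n_cases_augmented`.
#' @export
recovery_check <- function(config = cohort_config(), n_days = 10L,
                           step_days = 7L, model = model_config(),
                           threshold = 0.5, coverage = coverage_rule(),
                           keep_fold_details = FALSE) {
  cohort <- generate_cohort(config)
  ds <- build_dataset(cohort$tft, cohort$nights, n_days = n_days,
                      coverage = coverage)
  n_cases_obs <- nrow(ds$cases)
  ds <- augment_dataset(ds, step_days = step_days)
  preds <- loocv_predict(ds, config = model, threshold = threshold,
                         seed = config$seed,
                         keep_fold_details = keep_fold_details)
  cm <- confusion(preds)
  m <- metrics(cm)
  youden <- if (is.na(m$sensitivity) || is.na(m$specificity)) NA_real_
            else m$sensitivity + m$specificity - 100
  structure(
    list(predictions = preds, confusion = cm, metrics = m, youden = youden,
         n_pairs = sum(ds$pairs$origin == "observed"),
         n_pairs_usable = sum(ds$pairs$origin == "observed" & ds$pairs$usable),
         n_cases = n_cases_obs, n_cases_augmented = nrow(ds$cases)),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d usable pairs, %d -> %d cases\n",
              x$n_pairs_usable, x$n_cases, x$n_cases_augmented))
  print(x$metrics)
  invisible(x)
}
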