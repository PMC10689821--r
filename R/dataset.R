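#' Enumerate within-patient training/evaluation cases
#'
#' A case joins two HR-TFT pairs of the same patient: the referred pair
#' (whose TFT values are known to the model) and the target pair (whose
#' thyrotoxicosis status is the label). All ordered pairs of distinct
#' usable pairs are emitted, both directions; cross-patient combinations
#' never occur, and patients with fewer than two usable pairs contribute
#' nothing. With `include_interpolated = FALSE` only observed-observed
#' cases are produced; with `TRUE`, interpolated pairs participate as both
#' referred and target (training only -- evaluation never targets them).
#' The label derives solely from the target's free T4.
#'
#' @param pairs A pairs tibble from [build_pairs()] (possibly with
#'   interpolated rows appended).
#' @param include_interpolated Allow interpolated pairs into cases?
#' @param tsh_floor Passed to the quotient feature, see [featurize()].
#' @param ranges Reference ranges for the label.
#' @return A tibble of cases: identifiers (`patient_id`, `ref_date`,
#'   `tgt_date`, `ref_origin`, `tgt_origin`), the 8 feature columns of
#'   [hr_feature_names()], and logical `label`.
#' @export
enumerate_cases <- function(pairs, include_interpolated = FALSE,
                            tsh_floor = 0.025,
                            ranges = reference_ranges()) {
  keep <- pairs$usable
  if (!include_interpolated) keep <- keep & pairs$origin == "observed"
  p <- pairs[keep, , drop = FALSE]
  idx_by_patient <- split(seq_len(nrow(p)), p$patient_id)
  ri <- integer(0)
  ti <- integer(0)
  for (idx in idx_by_patient) {
    k <- length(idx)
    if (k < 2) next
    g <- expand.grid(r = idx, t = idx)
    g <- g[g$r != g$t, , drop = FALSE]
    ri <- c(ri, g$r)
    ti <- c(ti, g$t)
  }
  if (!length(ri)) return(empty_cases_tibble())
  d_mean <- p$hr_mean[ti] - p$hr_mean[ri]
  js <- vapply(seq_along(ri), function(i) {
    js_from_samples(p$samples[[ri[i]]], p$samples[[ti[i]]])
  }, numeric(1))
  out <- tibble::tibble(
    patient_id = p$patient_id[ri],
    ref_date = p$test_date[ri],
    tgt_date = p$test_date[ti],
    ref_origin = p$origin[ri],
    tgt_origin = p$origin[ti],
    ft4_ref = p$free_t4[ri],
    tsh_ref = p$tsh[ri],
    d_mean = d_mean,
    d_rsd = p$hr_rsd[ti] - p$hr_rsd[ri],
    d_skew = p$hr_skew[ti] - p$hr_skew[ri],
    d_kurt = p$hr_kurt[ti] - p$hr_kurt[ri],
    js_div = js,
    d_mean_over_tsh = d_mean / pmax(p$tsh[ri], tsh_floor),
    label = is_thyrotoxic(p$free_t4[ti], ranges)
  )
  out[order(out$patient_id, out$ref_date, out$tgt_date), ]
}

empty_cases_tibble <- function() {
  tibble::tibble(
    patient_id = character(), ref_date = as.Date(character()),
    tgt_date = as.Date(character()), ref_origin = character(),
    tgt_origin = character(), ft4_ref = numeric(), tsh_ref = numeric(),
    d_mean = numeric(), d_rsd = numeric(), d_skew = numeric(),
    d_kurt = numeric(), js_div = numeric(), d_mean_over_tsh = numeric(),
    label = logical()
  )
}

#' Interpolated HR-TFT pairs between two adjacent tests
#'
#' Creates synthetic TFT results on a regular grid strictly between two
#' consecutive tests of one patient: at dates `a + step_days, a +
#' 2*step_days, ...` strictly before `b`. Free T4 and TSH are linearly
#' interpolated in time between the endpoint values (optionally
#' log-linearly for TSH, which spans orders of magnitude); each synthetic
#' test is then paired with the actual sleep-HR window preceding its date.
#' Pairs failing window coverage are dropped. Grid endpoints are never
#' emitted, so endpoint values are reproduced only in the limit
#' (continuity), never duplicated.
#'
#' @param tft_a,tft_b One-row tibbles (or lists) with `patient_id`,
#'   `test_date`, `free_t4`, `tsh`; `tft_a` strictly earlier, same patient,
#'   consecutive in time (no test between them).
#' @param nights Sleep nights tibble for the patient (or whole cohort).
#' @param step_days Interpolation grid spacing in days.
#' @param n_days,coverage,include_anchor_morning Window construction
#'   parameters, as in [build_pairs()].
#' @param tsh_interp `"linear"` (on concentrations, default) or `"log"`.
#' @return A pairs tibble (usable rows only) with `origin = "interpolated"`.
#' @export
interpolate_pairs <- function(tft_a, tft_b, nights, step_days = 7L,
                              n_days = 10L, coverage = coverage_rule(),
                              include_anchor_morning = FALSE,
                              tsh_interp = c("linear", "log")) {
  tsh_interp <- match.arg(tsh_interp)
  a <- as.list(tft_a)
  b <- as.list(tft_b)
  da <- as.Date(a$test_date)
  db <- as.Date(b$test_date)
  if (!identical(a$patient_id, b$patient_id)) {
    abort("contract violation: interpolation endpoints belong to different patients")
  }
  if (da >= db) abort("contract violation: tft_a must precede tft_b")
  if (step_days < 1) abort("step_days must be >= 1")
  if (da + step_days >= db) return(empty_pairs_tibble())
  grid <- seq(da + step_days, db - 1, by = step_days)
  grid <- grid[grid > da & grid < db]
  if (!length(grid)) return(empty_pairs_tibble())
  frac <- as.numeric(grid - da) / as.numeric(db - da)
  ft4 <- a$free_t4 + frac * (b$free_t4 - a$free_t4)
  tsh <- if (tsh_interp == "log") {
    exp(log(max(a$tsh, 1e-6)) + frac * (log(max(b$tsh, 1e-6)) - log(max(a$tsh, 1e-6))))
  } else {
    a$tsh + frac * (b$tsh - a$tsh)
  }
  tfts <- tibble::tibble(patient_id = a$patient_id, test_date = grid,
                         free_t4 = ft4, tsh = tsh)
  out <- build_pairs(tfts, nights, n_days = n_days, coverage = coverage,
                     include_anchor_morning = include_anchor_morning)
  out$origin <- "interpolated"
  out[out$usable, , drop = FALSE]
}

#' Assemble a dataset of pairs and observed cases
#'
#' Runs the ingestion half of the pipeline: joins TFTs to their sleep-HR
#' windows and enumerates the observed within-patient cases. The returned
#' object also carries the night data and construction parameters so that
#' [augment_dataset()] can extend it.
#'
#' @inheritParams build_pairs
#' @inheritParams enumerate_cases
#' @return An object of class `thyro_dataset`: list with `pairs`, `cases`,
#'   `nights`, and the construction parameters.
#' @export
build_dataset <- function(tfts, nights, n_days = 10L,
                          coverage = coverage_rule(),
                          tsh_floor = 0.025,
                          ranges = reference_ranges(),
                          include_anchor_morning = FALSE) {
  pairs <- build_pairs(tfts, nights, n_days = n_days, coverage = coverage,
                       include_anchor_morning = include_anchor_morning)
  cases <- enumerate_cases(pairs, include_interpolated = FALSE,
                           tsh_floor = tsh_floor, ranges = ranges)
  structure(
    list(pairs = pairs, cases = cases, nights = nights, n_days = n_days,
         coverage = coverage, tsh_floor = tsh_floor, ranges = ranges,
         include_anchor_morning = include_anchor_morning,
         augmented = FALSE, step_days = NA_integer_),
    class = "thyro_dataset"
  )
}

#' @export
print.thyro_dataset <- function(x, ...) {
  n_obs <- sum(x$pairs$origin == "observed")
  n_int <- sum(x$pairs$origin == "interpolated")
  cat(sprintf(
    "<thyro_dataset> %d patient(s), %d observed pair(s) (%d usable), %d interpolated, %d case(s)%s\n",
    length(unique(x$pairs$patient_id)), n_obs,
    sum(x$pairs$usable & x$pairs$origin == "observed"), n_int,
    nrow(x$cases), if (x$augmented) " [augmented]" else ""))
  invisible(x)
}

#' Augment a dataset by interpolating between adjacent tests
#'
#' For every pair of consecutive observed tests of each patient, inserts
#' interpolated HR-TFT pairs on a `step_days` grid (see
#' [interpolate_pairs()]) and re-enumerates cases with interpolated pairs
#' allowed as both referred and target. Interpolated pairs are marked by
#' `origin` so evaluation can exclude them: they are never targets at
#' prediction time. The observed case set is always a subset of the
#' augmented one. If `step_days` exceeds every inter-test gap the dataset
#' is returned with no additions.
#'
#' @param dataset A `thyro_dataset` from [build_dataset()].
#' @param step_days Interpolation grid spacing in days.
#' @param tsh_interp Interpolation scale for TSH, see [interpolate_pairs()].
#' @return The augmented `thyro_dataset`.
#' @export
augment_dataset <- function(dataset, step_days = 7L,
                            tsh_interp = c("linear", "log")) {
  stopifnot(inherits(dataset, "thyro_dataset"))
  tsh_interp <- match.arg(tsh_interp)
  obs <- dataset$pairs[dataset$pairs$origin == "observed", , drop = FALSE]
  nights_by_patient <- split(dataset$nights, dataset$nights$patient_id)
  added <- list()
  for (pid in unique(obs$patient_id)) {
    po <- obs[obs$patient_id == pid, , drop = FALSE]
    po <- po[order(po$test_date), , drop = FALSE]
    if (nrow(po) < 2) next
    np <- nights_by_patient[[pid]]
    if (is.null(np)) next
    for (i in seq_len(nrow(po) - 1)) {
      added[[length(added) + 1L]] <- interpolate_pairs(
        po[i, ], po[i + 1, ], np, step_days = step_days,
        n_days = dataset$n_days, coverage = dataset$coverage,
        include_anchor_morning = dataset$include_anchor_morning,
        tsh_interp = tsh_interp)
    }
  }
  pairs <- dataset$pairs
  if (length(added)) pairs <- dplyr::bind_rows(pairs, added)
  dataset$pairs <- pairs
  dataset$cases <- enumerate_cases(pairs, include_interpolated = TRUE,
                                   tsh_floor = dataset$tsh_floor,
                                   ranges = dataset$ranges)
  dataset$augmented <- TRUE
  dataset$step_days <- as.integer(step_days)
  dataset
}

#' Serialize cases or pairs to CSV
#'
#' `write_cases_csv()` writes identifiers, origins, the 8 features and the
#' label; `read_cases_csv()` reads them back losslessly (full double
#' precision). `write_pairs_csv()` writes the pair table without the raw
#' sample vectors.
#'
#' @param cases,pairs Tibbles as produced by [enumerate_cases()] /
#'   [build_pairs()].
#' @param path Output file path.
#' @return The path (writers, invisibly) or a tibble (reader).
#' @export
write_cases_csv <- function(cases, path) {
  readr::write_csv(cases, path)
  invisible(path)
}

#' @rdname write_cases_csv
#' @export
read_cases_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    patient_id = readr::col_character(),
                    ref_date = readr::col_date(),
                    tgt_date = readr::col_date(),
                    ref_origin = readr::col_character(),
                    tgt_origin = readr::col_character(),
                    label = readr::col_logical(),
                    .default = readr::col_double()
                  ))
}

#' @rdname write_cases_csv
#' @export
write_pairs_csv <- function(pairs, path) {
  readr::write_csv(pairs[setdiff(names(pairs), "samples")], path)
  invisible(path)
}
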