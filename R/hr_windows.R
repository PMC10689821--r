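#' Minimum-coverage rule for a heart-rate window
#'
#' A window (and hence an HR-TFT pair) is usable when it contains at least
#' `min_nights` sleep nights and `min_samples` pooled heart-rate samples.
#' Moment and divergence estimates on fewer samples are unstable, so pairs
#' failing the rule are flagged rather than silently included.
#'
#' @param min_nights Minimum number of nights in the window.
#' @param min_samples Minimum pooled sample count across nights.
#' @return An object of class `coverage_rule`.
#' @export
coverage_rule <- function(min_nights = 3L, min_samples = 300L) {
  if (min_nights < 0 || min_samples < 0) abort("coverage thresholds must be >= 0")
  structure(list(min_nights = as.integer(min_nights),
                 min_samples = as.integer(min_samples)),
            class = "coverage_rule")
}

HR_BOUNDS <- c(20, 250) # physiologic validity bounds, bpm (exclusive)

filter_hr_samples <- function(samples) {
  keep <- samples > HR_BOUNDS[1] & samples < HR_BOUNDS[2] & !is.na(samples)
  list(samples = samples[keep], n_dropped = sum(!keep))
}

#' Assign sleep sessions to calendar dates
#'
#' A sleep session belongs to the calendar date on which it ends, so an
#' overnight sleep from 23:10 March 3 to 06:40 March 4 is the night of
#' March 4. Multiple sessions of one patient ending on the same date (for
#' example an overnight sleep plus an afternoon nap) are concatenated in
#' chronological order under that date. Heart-rate samples outside the open
#' interval (20, 250) bpm are dropped; the total dropped count is attached
#' as attribute `n_dropped` and reported.
#'
#' @param sessions A data frame with columns `patient_id`, `session_start`,
#'   `session_end` (POSIXct or ISO-8601 strings) and `samples` (list column
#'   of numeric heart-rate vectors, ordered in time within the session).
#' @return A tibble of sleep nights: `patient_id`, `date` (Date), `samples`
#'   (list column), `n_samples`; one row per (patient, date).
#' @export
assign_sessions_to_dates <- function(sessions) {
  stopifnot(is.data.frame(sessions))
  required <- c("patient_id", "session_start", "session_end", "samples")
  missing <- setdiff(required, names(sessions))
  if (length(missing)) {
    abort(paste0("sessions are missing columns: ", paste(missing, collapse = ", ")))
  }
  empty <- tibble::tibble(patient_id = character(), date = as.Date(character()),
                          samples = list(), n_samples = integer())
  if (nrow(sessions) == 0) return(empty)
  st <- sessions$session_start
  en <- sessions$session_end
  if (is.character(st)) st <- as.POSIXct(st, tz = "UTC")
  if (is.character(en)) en <- as.POSIXct(en, tz = "UTC")
  if (anyNA(st) || anyNA(en)) abort("unparseable session timestamps")
  if (any(en < st)) {
    abort(paste0("session end before start at rows: ",
                 paste(head(which(en < st), 10), collapse = ", ")))
  }
  date <- as.Date(format(en, "%Y-%m-%d"))
  ord <- order(sessions$patient_id, date, st)
  pid <- sessions$patient_id[ord]
  date <- date[ord]
  raw <- sessions$samples[ord]

  n_dropped <- 0L
  key <- paste(pid, date)
  groups <- split(seq_along(key), factor(key, levels = unique(key)))
  rows <- lapply(groups, function(idx) {
    pooled <- unlist(raw[idx], use.names = FALSE)
    f <- filter_hr_samples(pooled)
    n_dropped <<- n_dropped + f$n_dropped
    list(patient_id = pid[idx[1]], date = date[idx[1]], samples = f$samples)
  })
  out <- tibble::tibble(
    patient_id = unname(vapply(rows, `[[`, character(1), "patient_id")),
    date = as.Date(unname(vapply(rows, function(r) as.character(r$date),
                                 character(1)))),
    samples = unname(lapply(rows, `[[`, "samples")),
    n_samples = unname(vapply(rows, function(r) length(r$samples), integer(1)))
  )
  if (n_dropped > 0) {
    inform(sprintf("dropped %d heart-rate samples outside (%g, %g) bpm",
                   n_dropped, HR_BOUNDS[1], HR_BOUNDS[2]))
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Extract the sleep-HR window preceding an anchor date
#'
#' Returns the nights whose dates fall in the `n_days`-day span before
#' `anchor_date`. The default convention is the literal reading of "N days
#' prior to the test date": dates in `[anchor - n_days, anchor - 1]`.
#' Setting `include_anchor_morning = TRUE` shifts the span to
#' `[anchor - n_days + 1, anchor]`, counting the sleep that ends on the
#' morning of the anchor date itself (which still precedes a daytime blood
#' draw). Missing days are simply absent; no imputation is performed.
#'
#' @param nights A tibble of sleep nights as from
#'   [assign_sessions_to_dates()]; may contain several patients if
#'   `patient_id` is given.
#' @param anchor_date The date the window precedes (a `Date` or ISO string).
#' @param n_days Window length in days (>= 1).
#' @param patient_id Optional: restrict `nights` to this patient.
#' @param include_anchor_morning Window convention switch, see above.
#' @return An object of class `hr_window`: a list with `patient_id`,
#'   `anchor_date`, `n_days`, `nights` (tibble), `pooled_samples`,
#'   `n_nights`, `n_samples`.
#' @export
extract_window <- function(nights, anchor_date, n_days = 10L,
                           patient_id = NULL,
                           include_anchor_morning = FALSE) {
  if (n_days < 1) abort("n_days must be >= 1")
  anchor_date <- as.Date(anchor_date)
  if (!is.null(patient_id)) {
    nights <- nights[nights$patient_id == patient_id, , drop = FALSE]
  } else if (nrow(nights) > 0) {
    patient_id <- nights$patient_id[1]
    if (!all(nights$patient_id == patient_id)) {
      abort("nights span several patients; supply patient_id")
    }
  }
  offset <- if (include_anchor_morning) 1L else 0L
  lo <- anchor_date - n_days + offset
  hi <- anchor_date - 1L + offset
  keep <- nights$date >= lo & nights$date <= hi
  sel <- nights[keep, , drop = FALSE]
  sel <- sel[order(sel$date), , drop = FALSE]
  pooled <- unlist(sel$samples, use.names = FALSE)
  if (is.null(pooled)) pooled <- numeric(0)
  structure(
    list(patient_id = patient_id, anchor_date = anchor_date,
         n_days = as.integer(n_days), nights = sel,
         pooled_samples = pooled, n_nights = nrow(sel),
         n_samples = length(pooled)),
    class = "hr_window"
  )
}

#' @export
print.hr_window <- function(x, ...) {
  cat(sprintf("<hr_window> %s @ %s: %d night(s), %d sample(s) over %d days\n",
              x$patient_id %||% "?", format(x$anchor_date), x$n_nights,
              x$n_samples, x$n_days))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Builds one pair row (list) for a single TFT against pre-split nights.
build_one_pair <- function(pid, test_date, free_t4, tsh, nights_p, n_days,
                           coverage, include_anchor_morning, origin) {
  w <- extract_window(nights_p, test_date, n_days = n_days, patient_id = pid,
                      include_anchor_morning = include_anchor_morning)
  usable <- TRUE
  reason <- NA_character_
  if (w$n_nights == 0) {
    usable <- FALSE; reason <- "no_hr_data"
  } else if (w$n_nights < coverage$min_nights) {
    usable <- FALSE; reason <- "insufficient_nights"
  } else if (w$n_samples < coverage$min_samples) {
    usable <- FALSE; reason <- "insufficient_samples"
  }
  mom <- if (w$n_samples >= 2) compute_moments(w$pooled_samples) else
    c(mean = NA_real_, rsd = NA_real_, skew = NA_real_, kurt = NA_real_)
  list(patient_id = pid, test_date = test_date, free_t4 = free_t4, tsh = tsh,
       origin = origin, usable = usable, reason = reason,
       n_nights = w$n_nights, n_samples = w$n_samples,
       hr_mean = mom[["mean"]], hr_rsd = mom[["rsd"]],
       hr_skew = mom[["skew"]], hr_kurt = mom[["kurt"]],
       samples = w$pooled_samples)
}

pairs_rows_to_tibble <- function(rows) {
  tibble::tibble(
    patient_id = vapply(rows, `[[`, character(1), "patient_id"),
    test_date = as.Date(vapply(rows, function(r) as.character(r$test_date),
                               character(1))),
    free_t4 = vapply(rows, `[[`, numeric(1), "free_t4"),
    tsh = vapply(rows, `[[`, numeric(1), "tsh"),
    origin = vapply(rows, `[[`, character(1), "origin"),
    usable = vapply(rows, `[[`, logical(1), "usable"),
    reason = vapply(rows, `[[`, character(1), "reason"),
    n_nights = vapply(rows, `[[`, integer(1), "n_nights"),
    n_samples = vapply(rows, `[[`, integer(1), "n_samples"),
    hr_mean = vapply(rows, `[[`, numeric(1), "hr_mean"),
    hr_rsd = vapply(rows, `[[`, numeric(1), "hr_rsd"),
    hr_skew = vapply(rows, `[[`, numeric(1), "hr_skew"),
    hr_kurt = vapply(rows, `[[`, numeric(1), "hr_kurt"),
    samples = lapply(rows, `[[`, "samples")
  )
}

empty_pairs_tibble <- function() {
  pairs_rows_to_tibble(list())
}

#' Join TFT results to their preceding sleep-HR windows
#'
#' Builds one HR-TFT pair per thyroid function test: the test result plus
#' the pooled sleep heart-rate samples of the `n_days` window preceding the
#' test date. Pairs whose window fails the minimum-coverage rule are kept
#' in the output but flagged `usable = FALSE` with a `reason`
#' (`no_hr_data`, `insufficient_nights`, `insufficient_samples`); a TFT
#' with no HR data at all is flagged, never an error. Window moments are
#' precomputed per pair.
#'
#' @param tfts A tibble of TFT results (`patient_id`, `test_date`,
#'   `free_t4`, `tsh`), as from [read_tft_csv()].
#' @param nights A tibble of sleep nights, as from
#'   [assign_sessions_to_dates()].
#' @param n_days Window length in days.
#' @param coverage A [coverage_rule()].
#' @inheritParams extract_window
#' @return A tibble of pairs with columns `patient_id`, `test_date`,
#'   `free_t4`, `tsh`, `origin` ("observed"), `usable`, `reason`,
#'   `n_nights`, `n_samples`, the four window moments `hr_mean`, `hr_rsd`,
#'   `hr_skew`, `hr_kurt`, and the list column `samples`.
#' @export
build_pairs <- function(tfts, nights, n_days = 10L,
                        coverage = coverage_rule(),
                        include_anchor_morning = FALSE) {
  validate_tft_values(tfts$free_t4, tfts$tsh)
  if (nrow(tfts) == 0) return(empty_pairs_tibble())
  nights_by_patient <- split(nights, nights$patient_id)
  rows <- lapply(seq_len(nrow(tfts)), function(i) {
    pid <- tfts$patient_id[i]
    np <- nights_by_patient[[pid]]
    if (is.null(np)) np <- nights[0, , drop = FALSE]
    build_one_pair(pid, as.Date(tfts$test_date[i]), tfts$free_t4[i],
                   tfts$tsh[i], np, n_days, coverage,
                   include_anchor_morning, origin = "observed")
  })
  pairs_rows_to_tibble(rows)
}

#' Read per-sample sleep heart-rate CSV
#'
#' One row per heart-rate sample with header
#' `patient_id,session_start,session_end,timestamp,hr_bpm` (ISO-8601
#' timestamps). Samples are regrouped into sessions and assigned to dates
#' with [assign_sessions_to_dates()].
#'
#' @param path Path to a CSV file.
#' @return A tibble of sleep nights.
#' @export
read_sleep_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          patient_id = readr::col_character(),
                          session_start = readr::col_datetime(),
                          session_end = readr::col_datetime(),
                          timestamp = readr::col_datetime(),
                          hr_bpm = readr::col_double()
                        ))
  required <- c("patient_id", "session_start", "session_end", "timestamp", "hr_bpm")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("sleep CSV is missing columns: ", paste(missing, collapse = ", ")))
  }
  df <- df[order(df$patient_id, df$session_start, df$timestamp), ]
  key <- paste(df$patient_id, df$session_start, df$session_end)
  groups <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  sessions <- tibble::tibble(
    patient_id = unname(vapply(groups, function(i) df$patient_id[i[1]],
                               character(1))),
    session_start = as.POSIXct(
      unname(vapply(groups, function(i) as.character(df$session_start[i[1]]),
                    character(1))), tz = "UTC"),
    session_end = as.POSIXct(
      unname(vapply(groups, function(i) as.character(df$session_end[i[1]]),
                    character(1))), tz = "UTC"),
    samples = unname(lapply(groups, function(i) df$hr_bpm[i]))
  )
  assign_sessions_to_dates(sessions)
}

#' Read or write pre-aggregated sleep nights as JSON
#'
#' The JSON form carries, per patient, a list of `{date, samples}` records
#' with sessions already assigned to the dates their sleep ends on. This is
#' the compact interchange format the synthetic-cohort generator writes.
#'
#' @param path JSON file path.
#' @return `read_sleep_json()` returns a tibble of sleep nights;
#'   `write_sleep_json()` returns `path` invisibly.
#' @export
read_sleep_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- list()
  for (pid in names(x)) {
    for (night in x[[pid]]) {
      f <- filter_hr_samples(as.numeric(unlist(night$samples)))
      rows[[length(rows) + 1L]] <- list(
        patient_id = pid, date = as.Date(night$date), samples = f$samples)
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(patient_id = character(), date = as.Date(character()),
                          samples = list(), n_samples = integer()))
  }
  out <- tibble::tibble(
    patient_id = vapply(rows, `[[`, character(1), "patient_id"),
    date = as.Date(vapply(rows, function(r) as.character(r$date), character(1))),
    samples = lapply(rows, `[[`, "samples"),
    n_samples = vapply(rows, function(r) length(r$samples), integer(1))
  )
  out[order(out$patient_id, out$date), ]
}

#' @rdname read_sleep_json
#' @param nights A tibble of sleep nights.
#' @export
write_sleep_json <- function(nights, path) {
  by_patient <- split(nights, nights$patient_id)
  payload <- lapply(by_patient, function(np) {
    lapply(seq_len(nrow(np)), function(i) {
      list(date = as.character(np$date[i]),
           samples = as.numeric(np$samples[[i]]))
    })
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
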