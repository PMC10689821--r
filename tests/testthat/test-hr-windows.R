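sessions_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(
    patient_id = vapply(rows, `[[`, character(1), 1),
    session_start = as.POSIXct(vapply(rows, `[[`, character(1), 2), tz = "UTC"),
    session_end = as.POSIXct(vapply(rows, `[[`, character(1), 3), tz = "UTC"),
    samples = lapply(rows, `[[`, 4)
  )
}

test_that("a sleep session belongs to the date its sleep ends", {
  nights <- assign_sessions_to_dates(sessions_tbl(
    list("p1", "2023-03-03 23:10:00", "2023-03-04 06:40:00", c(60, 62, 61))
  ))
  expect_equal(nrow(nights), 1)
  expect_equal(nights$date, as.Date("2023-03-04"))
  expect_equal(nights$samples[[1]], c(60, 62, 61))
})

test_that("sessions ending on the same date are concatenated in time order", {
  nights <- assign_sessions_to_dates(sessions_tbl(
    list("p1", "2023-03-04 13:00:00", "2023-03-04 14:00:00", c(70, 71)),
    list("p1", "2023-03-03 23:10:00", "2023-03-04 06:40:00", c(60, 61))
  ))
  expect_equal(nrow(nights), 1)
  # overnight session started earlier, so its samples come first
  expect_equal(nights$samples[[1]], c(60, 61, 70, 71))
  expect_equal(nights$n_samples, 4L)
})

test_that("empty input, bad timestamps and invalid samples are handled", {
  expect_equal(nrow(assign_sessions_to_dates(sessions_tbl())), 0)
  expect_error(assign_sessions_to_dates(sessions_tbl(
    list("p1", "2023-03-04 06:00:00", "2023-03-03 23:00:00", c(60)))),
    "end before start")
  # out-of-physiologic-range samples are dropped with a count
  nights <- suppressMessages(assign_sessions_to_dates(sessions_tbl(
    list("p1", "2023-03-03 23:00:00", "2023-03-04 06:00:00",
         c(60, 15, 260, 61, 20, 250)))))
  expect_equal(nights$samples[[1]], c(60, 61))
  expect_equal(attr(nights, "n_dropped"), 4L)
})

test_that("window extraction takes the N days before the anchor", {
  withr::with_seed(1, {
    nights <- make_nights("p1", "2023-03-20", n_nights = 19)
  })
  w <- extract_window(nights, "2023-03-15", n_days = 10)
  expect_equal(w$n_nights, 10)
  expect_equal(range(w$nights$date),
               as.Date(c("2023-03-05", "2023-03-14")))
  # anchor-morning convention shifts the span by one day
  w2 <- extract_window(nights, "2023-03-15", n_days = 10,
                       include_anchor_morning = TRUE)
  expect_equal(range(w2$nights$date),
               as.Date(c("2023-03-06", "2023-03-15")))
})

test_that("sparse and empty windows are representable without error", {
  withr::with_seed(2, {
    nights <- make_nights("p1", "2023-03-20", n_nights = 19)
  })
  sparse <- nights[nights$date %in% as.Date(c("2023-03-06", "2023-03-09")), ]
  w <- extract_window(sparse, "2023-03-15", n_days = 10)
  expect_equal(w$n_nights, 2)
  w0 <- extract_window(sparse, "2023-06-01", n_days = 10)
  expect_equal(w0$n_nights, 0)
  expect_equal(w0$n_samples, 0)
  expect_error(extract_window(sparse, "2023-03-15", n_days = 0), "n_days")
})

test_that("window extraction is order-independent and conservative", {
  withr::with_seed(3, {
    nights <- make_nights("p1", "2023-04-01", n_nights = 25)
    for (rep in 1:5) {
      anchor <- as.Date("2023-03-10") + sample(0:20, 1)
      n_days <- sample(1:12, 1)
      shuffled <- nights[sample(nrow(nights)), ]
      w1 <- extract_window(nights, anchor, n_days)
      w2 <- extract_window(shuffled, anchor, n_days)
      expect_equal(w1$pooled_samples, w2$pooled_samples)
      # no night outside the span, and sample count is conserved
      expect_true(all(w1$nights$date >= anchor - n_days &
                        w1$nights$date <= anchor - 1))
      expect_equal(w1$n_samples, sum(w1$nights$n_samples))
    }
  })
})

test_that("pair construction flags insufficient coverage instead of failing", {
  withr::with_seed(4, {
    nights <- make_nights("p1", "2023-03-15", n_nights = 10)
  })
  tfts <- tibble::tibble(
    patient_id = c("p1", "p1", "p2"),
    test_date = as.Date(c("2023-03-15", "2023-06-01", "2023-03-15")),
    free_t4 = c(2.0, 1.2, 1.3), tsh = c(0.03, 2.0, 1.0))
  pairs <- build_pairs(tfts, nights)
  expect_equal(nrow(pairs), 3)
  expect_equal(pairs$usable, c(TRUE, FALSE, FALSE))
  expect_equal(pairs$reason, c(NA, "no_hr_data", "no_hr_data"))
  # usable pair carries pooled samples and moments
  expect_equal(pairs$n_nights[1], 10L)
  expect_equal(pairs$hr_mean[1], mean(pairs$samples[[1]]))

  # coverage thresholds are configurable
  strict <- build_pairs(tfts, nights, coverage = coverage_rule(11, 300))
  expect_equal(strict$reason[1], "insufficient_nights")
})

test_that("per-sample CSV and aggregated JSON dialects agree", {
  withr::with_seed(5, {
    nights <- make_nights("pX", "2023-03-15", n_nights = 3, len = 30)
  })
  json_path <- withr::local_tempfile(fileext = ".json")
  write_sleep_json(nights, json_path)
  back <- read_sleep_json(json_path)
  expect_equal(back$date, nights$date)
  expect_equal(back$samples, lapply(nights$samples, as.numeric))

  # per-sample CSV: two sessions, one overnight
  csv_path <- withr::local_tempfile(fileext = ".csv")
  df <- tibble::tibble(
    patient_id = "pY",
    session_start = rep(as.POSIXct(c("2023-03-03 23:00:00",
                                     "2023-03-04 13:00:00"), tz = "UTC"),
                        each = 3),
    session_end = rep(as.POSIXct(c("2023-03-04 06:00:00",
                                   "2023-03-04 13:30:00"), tz = "UTC"),
                      each = 3),
    timestamp = as.POSIXct("2023-03-03 23:00:00", tz = "UTC") + seq(0, 50, 10),
    hr_bpm = c(60, 61, 62, 70, 71, 72))
  readr::write_csv(df, csv_path)
  nights2 <- read_sleep_csv(csv_path)
  expect_equal(nrow(nights2), 1)
  expect_equal(nights2$samples[[1]], c(60, 61, 62, 70, 71, 72))
})
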