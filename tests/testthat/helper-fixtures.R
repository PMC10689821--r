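# Fixture builders shared across test files. All randomness is seeded at
# the call site via withr::with_seed so test files stay order-independent.

# Nights with a given per-night mean for one patient on consecutive dates
# ending the day before `anchor`.
make_nights <- function(patient_id, anchor, n_nights = 10, mean_bpm = 65,
                        sd_bpm = 5, len = 120) {
  anchor <- as.Date(anchor)
  dates <- anchor - rev(seq_len(n_nights))
  tibble::tibble(
    patient_id = patient_id,
    date = dates,
    samples = lapply(seq_len(n_nights), function(i) {
      pmin(pmax(round(stats::rnorm(len, mean_bpm, sd_bpm)), 21), 249)
    }),
    n_samples = len
  )
}

# A small cohort where window mean HR tracks free T4 tightly: visits a month
# apart, thyrotoxic visits (ft4 > 1.78) get an HR offset of slope*(ft4-1.335).
# Returns list(tft, nights).
make_coupled_cohort <- function(n_patients = 6, visits = 3, slope = 22,
                                sd_bpm = 4, len = 150) {
  tfts <- list()
  nights <- list()
  for (p in seq_len(n_patients)) {
    pid <- sprintf("S%02d", p)
    base <- 60 + (p %% 3)
    # alternate trajectories so both classes appear at several visit slots
    f_traj <- if (p %% 2 == 0) seq(2.6, 1.2, length.out = visits)
              else seq(1.1, 1.5, length.out = visits)
    dates <- as.Date("2023-05-01") + 30 * (seq_len(visits) - 1) + p
    for (v in seq_len(visits)) {
      tfts[[length(tfts) + 1]] <- tibble::tibble(
        patient_id = pid, test_date = dates[v],
        free_t4 = f_traj[v],
        tsh = max(0.025, 1.5 * 10^(-1.8 * (f_traj[v] - 1.22))))
      nights[[length(nights) + 1]] <- make_nights(
        pid, dates[v], n_nights = 10,
        mean_bpm = base + slope * (f_traj[v] - 1.335),
        sd_bpm = sd_bpm, len = len)
    }
  }
  list(tft = dplyr::bind_rows(tfts), nights = dplyr::bind_rows(nights))
}

# Strongly separable training cases: positives have d_mean near +15 bpm,
# negatives near 0; other features are noise.
make_separable_cases <- function(n = 400, balance = 0.5) {
  n_pos <- round(n * balance)
  label <- c(rep(TRUE, n_pos), rep(FALSE, n - n_pos))
  d_mean <- ifelse(label, stats::rnorm(n, 15, 2), stats::rnorm(n, 0, 2))
  tibble::tibble(
    patient_id = sprintf("C%04d", seq_len(n)),
    ref_date = as.Date("2023-01-01"),
    tgt_date = as.Date("2023-02-01"),
    ref_origin = "observed", tgt_origin = "observed",
    ft4_ref = stats::runif(n, 0.9, 1.7),
    tsh_ref = stats::runif(n, 0.3, 4),
    d_mean = d_mean,
    d_rsd = stats::rnorm(n, 0, 0.02),
    d_skew = stats::rnorm(n, 0, 0.3),
    d_kurt = stats::rnorm(n, 0, 0.5),
    js_div = stats::runif(n, 0, 0.5),
    d_mean_over_tsh = d_mean / pmax(stats::runif(n, 0.3, 4), 0.025),
    label = label
  )
}

# The worked two-patient LOOCV fixture: patients A and B, three pairs each,
# full HR coverage, distinct dates.
make_two_patient_dataset <- function() {
  c6 <- make_coupled_cohort(n_patients = 2, visits = 3)
  c6$tft$patient_id <- rep(c("A", "B"), each = 3)
  c6$nights$patient_id <- rep(c("A", "B"), each = 30)
  build_dataset(c6$tft, c6$nights)
}
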