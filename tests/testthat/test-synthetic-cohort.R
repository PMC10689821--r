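test_that("generation is reproducible from the seed", {
  cfg <- cohort_config(n_patients = 2, seed = 99)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$tft, c2$tft)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$nights, c2$nights)
  # and files are byte-identical across runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in c("tft.csv", "sleep.json", "truth.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed gives different data
  c3 <- generate_cohort(cohort_config(n_patients = 2, seed = 100))
  expect_false(identical(c1$tft, c3$tft))
})

test_that("generated files round-trip through the ingestion readers", {
  cfg <- cohort_config(n_patients = 3, seed = 5, missing_night_prob = 0)
  cohort <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$tft), nrow(cohort$tft))
  expect_equal(back$tft$free_t4, cohort$tft$free_t4)
  # zero dropped records at missing_night_prob = 0
  expect_equal(nrow(back$nights), nrow(cohort$nights))
  expect_equal(sum(back$nights$n_samples), sum(cohort$nights$n_samples))
  expect_equal(lapply(back$nights$samples, as.integer), cohort$nights$samples)
  # every TFT has full window coverage by construction
  pairs <- build_pairs(back$tft, back$nights)
  expect_true(all(pairs$usable))
})

test_that("TFT schedule respects the visit-count mix and spacing", {
  cohort <- generate_cohort(cohort_config(n_patients = 60, seed = 6))
  counts <- table(table(cohort$tft$patient_id))
  expect_true(all(names(counts) %in% c("3", "4")))
  gaps <- unlist(lapply(split(cohort$tft, cohort$tft$patient_id), function(d) {
    diff(sort(d$test_date))
  }))
  expect_true(all(gaps >= 28))
})

test_that("night means track latent free T4 at the configured slope", {
  cfg <- cohort_config(n_patients = 25, seed = 21, hr_night_jitter = 3,
                       hr_night_noise = 5)
  cohort <- generate_cohort(cfg)
  # per-patient regression of night-mean HR on same-day latent fT4;
  # latent fT4 at night dates is reconstructed from visit-day truth by
  # using only thyrotoxic patients with a wide fT4 range (identifiable slope)
  slopes <- c()
  for (pid in unique(cohort$nights$patient_id)) {
    tr <- cohort$truth[cohort$truth$patient_id == pid, ]
    if (diff(range(tr$latent_ft4)) < 0.4) next
    np <- cohort$nights[cohort$nights$patient_id == pid, ]
    night_mean <- vapply(np$samples, mean, numeric(1))
    # visit-day latent values interpolated to night dates (smooth decay)
    f_at <- stats::approx(as.numeric(tr$date), tr$latent_ft4,
                          xout = as.numeric(np$date), rule = 2)$y
    slopes <- c(slopes, stats::coef(stats::lm(night_mean ~ f_at))[2])
  }
  expect_gt(length(slopes), 3)
  expect_lt(abs(median(slopes) - cfg$hr_coupling_slope) /
              cfg$hr_coupling_slope, 0.2)
})

test_that("zero coupling decouples heart rate from free T4", {
  cohort <- generate_cohort(cohort_config(n_patients = 175, seed = 8,
                                          hr_coupling_slope = 0))
  pairs <- build_pairs(cohort$tft, cohort$nights)
  pairs <- pairs[pairs$usable, ]
  r <- stats::cor(pairs$free_t4, pairs$hr_mean)
  expect_lt(abs(r), 0.1)
})

test_that("the visit-state mix converges to the configured proportions", {
  # law-of-large-numbers check against the cohort the generator emulates:
  # ~15% overt thyrotoxic, ~40% subclinical thyrotoxic, ~35% euthyroid,
  # ~5% subclinical and ~5% overt hypothyroid
  cohort <- generate_cohort(cohort_config(n_patients = 2000, seed = 31),
                            hr = FALSE)
  mix <- 100 * prop.table(table(factor(cohort$truth$state,
                                       levels = thyroid_states())))
  target <- c(overt_thyrotoxicosis = 15.3, subclinical_thyrotoxicosis = 39.7,
              euthyroid = 34.6, subclinical_hypothyroidism = 5.0,
              overt_hypothyroidism = 5.4)
  expect_true(all(abs(mix[names(target)] - target) <= 3))
})

test_that("thyrotoxic-to-euthyroid transitions leave a heart-rate signature", {
  # referred = late (near-euthyroid) visit, target = first (thyrotoxic)
  # visit: the mean-HR change must be positive and the distributions must
  # diverge, across many generator seeds
  hits <- 0L
  evaluated <- 0L
  for (s in 1:50) {
    cfg <- cohort_config(
      n_patients = 1, seed = 1000 + s,
      group_probs = c(thyrotoxic = 1, euthyroid = 0, hypothyroid = 0))
    cohort <- generate_cohort(cfg)
    pairs <- build_pairs(cohort$tft, cohort$nights)
    pairs <- pairs[pairs$usable, ]
    if (nrow(pairs) < 2) next
    ref <- pairs[nrow(pairs), ] # latest visit, lowest fT4
    tgt <- pairs[1, ]           # first visit, thyrotoxic
    if (tgt$free_t4 - ref$free_t4 < 0.3) next # decay too shallow to call
    evaluated <- evaluated + 1L
    f <- featurize(ref, tgt)
    if (f[["d_mean"]] > 0 && f[["js_div"]] > 0) hits <- hits + 1L
  }
  expect_gt(evaluated, 25)
  expect_gt(hits / evaluated, 0.95)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(missing_night_prob = 1.5), "missing_night_prob")
  expect_error(cohort_config(group_probs = c(thyrotoxic = 0.5,
                                             euthyroid = 0.2,
                                             hypothyroid = 0.1)),
               "group_probs")
  expect_error(cohort_config(hr_coupling_slope = -1), "hr_coupling_slope")
})
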