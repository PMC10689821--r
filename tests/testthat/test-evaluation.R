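test_that("the LOOCV fold for a target excludes exactly its cases", {
  withr::with_seed(40, {
    ds <- make_two_patient_dataset()
  })
  # no augmentation: 12 cases total, 6 per patient
  expect_equal(nrow(ds$cases), 12)
  dates_a <- sort(unique(ds$cases$ref_date[ds$cases$patient_id == "A"]))
  ta2 <- dates_a[2]

  preds <- loocv_predict(ds, config = model_config(nrounds = 20),
                         keep_fold_details = TRUE)
  expect_equal(nrow(preds), 6)
  fold <- NULL
  for (f in attr(preds, "fold_details")) {
    if (f$patient_id == "A" && f$target_date == ta2) fold <- f
  }
  expect_false(is.null(fold))
  # training keys: A keeps only Ta1<->Ta3; B keeps all 6 of its cases
  keys <- fold$train_keys
  expect_equal(fold$n_excluded, 4) # Ta1->Ta2, Ta3->Ta2, Ta2->Ta1, Ta2->Ta3
  expect_equal(nrow(keys), 8)
  a_keys <- keys[keys$patient_id == "A", ]
  expect_equal(nrow(a_keys), 2)
  expect_true(all(a_keys$ref_date != ta2 & a_keys$tgt_date != ta2))
  expect_equal(sort(unique(c(a_keys$ref_date, a_keys$tgt_date))),
               dates_a[c(1, 3)])
  expect_equal(sum(keys$patient_id == "B"), 6)
  # the tested target had two referred pairs and averaged their probabilities
  target_row <- preds[preds$patient_id == "A" & preds$target_date == ta2, ]
  expect_equal(target_row$n_referred, 2L)
  expect_equal(target_row$averaged_probability,
               mean(target_row$referred_probs[[1]]))
})

test_that("no fold's training cases ever reference the held-out pair", {
  withr::with_seed(41, {
    co <- make_coupled_cohort(n_patients = 5, visits = 3)
  })
  ds <- augment_dataset(build_dataset(co$tft, co$nights), step_days = 7)
  preds <- loocv_predict(ds, config = model_config(nrounds = 20),
                         keep_fold_details = TRUE)
  for (f in attr(preds, "fold_details")) {
    keys <- f$train_keys
    touches <- keys$patient_id == f$patient_id &
      (keys$ref_date == f$target_date | keys$tgt_date == f$target_date)
    expect_equal(sum(touches), 0)
  }
})

test_that("confusion counting matches a brute-force recount on random inputs", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      n <- sample(20:100, 1)
      preds <- tibble::tibble(
        decision = sample(c(TRUE, FALSE), n, replace = TRUE),
        true_label = sample(c(TRUE, FALSE), n, replace = TRUE),
        true_state = sample(thyroid_states(), n, replace = TRUE))
      # labels and states must cohere for the exclusion variant
      preds$true_state[preds$true_label] <- "overt_thyrotoxicosis"
      preds$true_state[!preds$true_label & preds$true_state ==
                         "overt_thyrotoxicosis"] <- "euthyroid"
      cm <- confusion(preds)
      oracle <- c(tp = 0, fn = 0, fp = 0, tn = 0)
      for (i in seq_len(n)) {
        cell <- if (preds$true_label[i] && preds$decision[i]) "tp"
                else if (preds$true_label[i]) "fn"
                else if (preds$decision[i]) "fp" else "tn"
        oracle[cell] <- oracle[cell] + 1
      }
      expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]), oracle)
      expect_equal(cm$tp + cm$fn + cm$fp + cm$tn, n)

      # excluding subclinical thyrotoxicosis never touches tp or fn
      cme <- confusion(preds, exclude_subclinical = TRUE)
      expect_equal(cme$tp, cm$tp)
      expect_equal(cme$fn, cm$fn)
      n_sub <- sum(preds$true_state == "subclinical_thyrotoxicosis")
      expect_equal(cme$fp + cme$tn, cm$fp + cm$tn - n_sub)
    }
  })
})

test_that("diagnostic metrics reproduce the worked confusion tables", {
  m1 <- metrics(confusion_matrix(87, 14, 79, 482))
  expect_equal(round(m1$sensitivity, 2), 86.14)
  expect_equal(round(m1$specificity, 2), 85.92)
  expect_equal(round(m1$ppv, 2), 52.41)
  expect_equal(round(m1$npv, 2), 97.18)

  m2 <- metrics(confusion_matrix(87, 14, 5, 285))
  expect_equal(round(m2$sensitivity, 2), 86.14)
  expect_equal(round(m2$specificity, 2), 98.28)
  expect_equal(round(m2$ppv, 2), 94.57)
  expect_equal(round(m2$npv, 2), 95.32)

  # zero denominators are undefined, never zero
  m3 <- metrics(confusion_matrix(0, 0, 0, 10))
  expect_true(is.na(m3$sensitivity))
  expect_true(is.na(m3$ppv))
  expect_equal(m3$specificity, 100)
  expect_equal(m3$npv, 100)

  expect_error(confusion_matrix(-1, 0, 0, 0), "non-negative")
})

test_that("averaged probability is the arithmetic mean over referred pairs", {
  expect_equal(mean(c(0.2, 0.8)), 0.5)
  withr::with_seed(43, {
    ds <- make_two_patient_dataset()
  })
  preds <- loocv_predict(ds, config = model_config(nrounds = 10))
  expect_equal(preds$averaged_probability,
               vapply(preds$referred_probs, mean, numeric(1)))
  expect_equal(preds$decision, preds$averaged_probability >= 0.5)
  expect_true(all(preds$averaged_probability >= 0 &
                    preds$averaged_probability <= 1))
})

test_that("group comparisons follow the reporting conventions", {
  withr::with_seed(44, {
    x1 <- stats::rnorm(100)
    x2 <- stats::rnorm(100, 2)
  })
  # identical groups: p near 1
  same <- compare_groups(c(x1, x1), rep(c("a", "b"), each = 100),
                         type = "normal")
  expect_gt(same$p_value, 0.99)
  # well-separated normals: decisive
  sep <- compare_groups(c(x1, x2), rep(c("a", "b"), each = 100))
  expect_lt(sep$p_value, 0.001)
  expect_equal(sep$test, "Student t")
  # skewed data fall back to the rank-sum test
  withr::with_seed(45, {
    y <- c(stats::rlnorm(80), stats::rlnorm(80, 1.5))
  })
  sk <- compare_groups(y, rep(c("a", "b"), each = 80))
  expect_equal(sk$test, "Wilcoxon rank-sum")
  # proportions: chi-square on 82/100 vs 33/100
  pr <- compare_groups(c(rep(TRUE, 82), rep(FALSE, 18),
                         rep(TRUE, 33), rep(FALSE, 67)),
                       rep(c("a", "b"), each = 100))
  expect_equal(pr$test, "chi-square")
  expect_lt(pr$p_value, 0.001)
  expect_error(compare_groups(1:3, c("a", "a", "b")), "insufficient")
})

test_that("window sweep runs both modes and is consistent at N = 10", {
  withr::with_seed(46, {
    co <- make_coupled_cohort(n_patients = 4, visits = 3)
  })
  cfg <- model_config(nrounds = 30)
  joint <- window_sweep(co$tft, co$nights, day_lengths = c(5, 10),
                        mode = "joint", config = cfg)
  fixed <- window_sweep(co$tft, co$nights, day_lengths = c(5, 10),
                        mode = "fixed_train_10", config = cfg)
  expect_equal(nrow(joint), 2)
  expect_equal(nrow(fixed), 2)
  # at N = 10 the two modes coincide (and equal the headline run)
  j10 <- joint[joint$n_days == 10, ]
  f10 <- fixed[fixed$n_days == 10, ]
  expect_equal(as.data.frame(j10[-1]), as.data.frame(f10[-1]))
  ds <- augment_dataset(build_dataset(co$tft, co$nights), step_days = 7)
  headline <- metrics(confusion(loocv_predict(ds, config = cfg)))
  expect_equal(j10$sensitivity, headline$sensitivity)
  expect_equal(j10$specificity, headline$specificity)
  # single length gives a single row
  one <- window_sweep(co$tft, co$nights, day_lengths = 10, mode = "joint",
                      config = cfg)
  expect_equal(nrow(one), 1)
  expect_error(window_sweep(co$tft, co$nights, day_lengths = 0), "1..30")
})
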