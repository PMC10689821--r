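#' Modified leave-one-out cross-validation with target-pair exclusion
#'
#' Evaluates the system the way it would be used: for each observed usable
#' pair P taken as the target, a model is trained on every case -- observed
#' and interpolated, from all patients -- EXCEPT those that involve P as
#' referred or target, and P's thyrotoxicosis probability is the average
#' of the predictions of the cases Q -> P over the patient's other observed
#' pairs Q. Excluding every case touching P (not only the tested direction)
#' keeps the held-out pair's heart-rate data and label out of training
#' entirely. One model is fitted per target pair: all test cases of a fold
#' share the same exclusion set, so per-case refitting would produce the
#' identical model at many times the cost. Patients with a single usable
#' observed pair cannot be evaluated and are skipped with a warning. A
#' degenerate fold whose training pool contains a single class (possible
#' only on very small cohorts) predicts the empirical prior instead of
#' fitting.
#'
#' @param dataset A `thyro_dataset`, normally after [augment_dataset()].
#' @param config A [model_config()].
#' @param threshold Decision threshold on the averaged probability.
#' @param seed Seed passed to each fold's model fit.
#' @param collect_importance Record per-fold gain/split importance tables
#'   (retrievable via [feature_importance()] on attribute `fold_models`,
#'   or directly as attribute `importance`).
#' @param keep_fold_details Store per-fold training-case identifiers for
#'   leakage audits (memory-proportional to folds x cases).
#' @return A tibble of class `loocv_predictions`, one row per evaluated
#'   target pair: `patient_id`, `target_date`, `free_t4`, `tsh`,
#'   `n_referred`, `referred_probs` (list), `averaged_probability`,
#'   `decision`, `true_label`, `true_state`. Attributes: `threshold`,
#'   `n_skipped`, optionally `fold_details` and `importance`.
#' @export
loocv_predict <- function(dataset, config = model_config(), threshold = 0.5,
                          seed = 1L, collect_importance = FALSE,
                          keep_fold_details = FALSE) {
  stopifnot(inherits(dataset, "thyro_dataset"))
  cases <- dataset$cases
  pairs <- dataset$pairs
  obs <- pairs[pairs$origin == "observed" & pairs$usable, , drop = FALSE]
  counts <- table(obs$patient_id)
  single <- names(counts)[counts < 2]
  if (length(single)) {
    warn(sprintf("%d patient(s) with a single usable pair skipped: %s",
                 length(single), paste(head(single, 5), collapse = ", ")))
  }
  targets <- obs[obs$patient_id %in% names(counts)[counts >= 2], , drop = FALSE]
  n <- nrow(targets)
  fold_details <- if (keep_fold_details) vector("list", n) else NULL
  importances <- if (collect_importance) vector("list", n) else NULL
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- targets$patient_id[i]
    tdate <- targets$test_date[i]
    involves_target <- cases$patient_id == pid &
      (cases$ref_date == tdate | cases$tgt_date == tdate)
    train <- cases[!involves_target, , drop = FALSE]
    test <- cases[cases$patient_id == pid & cases$tgt_date == tdate &
                    cases$ref_origin == "observed" &
                    cases$tgt_origin == "observed", , drop = FALSE]
    if (length(unique(train$label)) < 2) {
      # degenerate fold (single-class training pool, only possible on very
      # small cohorts): fall back to the empirical prior
      model <- NULL
      probs <- rep(mean(train$label), nrow(test))
    } else {
      model <- fit_classifier(train, config = config, seed = seed,
                              warn_small = FALSE)
      probs <- predict_proba(model, test)
    }
    avg <- mean(probs)
    rows[[i]] <- list(
      patient_id = pid, target_date = tdate,
      free_t4 = targets$free_t4[i], tsh = targets$tsh[i],
      n_referred = nrow(test), referred_probs = probs,
      averaged_probability = avg, decision = avg >= threshold)
    if (keep_fold_details) {
      fold_details[[i]] <- list(
        patient_id = pid, target_date = tdate,
        n_train = nrow(train), n_excluded = sum(involves_target),
        train_keys = train[, c("patient_id", "ref_date", "tgt_date")])
    }
    if (collect_importance && !is.null(model)) {
      importances[[i]] <- single_model_importance(model)
    }
  }
  out <- tibble::tibble(
    patient_id = vapply(rows, `[[`, character(1), "patient_id"),
    target_date = as.Date(vapply(rows, function(r) as.character(r$target_date),
                                 character(1))),
    free_t4 = vapply(rows, `[[`, numeric(1), "free_t4"),
    tsh = vapply(rows, `[[`, numeric(1), "tsh"),
    n_referred = vapply(rows, `[[`, integer(1), "n_referred"),
    referred_probs = lapply(rows, `[[`, "referred_probs"),
    averaged_probability = vapply(rows, `[[`, numeric(1), "averaged_probability"),
    decision = vapply(rows, `[[`, logical(1), "decision")
  )
  out$true_label <- is_thyrotoxic(out$free_t4, dataset$ranges)
  out$true_state <- classify_state(out$free_t4, out$tsh, dataset$ranges)
  class(out) <- c("loocv_predictions", class(out))
  attr(out, "threshold") <- threshold
  attr(out, "n_skipped") <- length(single)
  if (keep_fold_details) attr(out, "fold_details") <- fold_details
  if (collect_importance) {
    importances <- Filter(Negate(is.null), importances)
    if (length(importances)) {
      attr(out, "importance") <- aggregate_importances(importances)
    }
  }
  out
}

aggregate_importances <- function(per_model) {
  agg <- per_model[[1]][, "feature", drop = FALSE]
  for (col in c("gain", "split", "rank_gain", "rank_split", "rank_combined")) {
    agg[[col]] <- rowMeans(vapply(per_model, `[[`, numeric(nrow(agg)), col))
  }
  agg <- agg[order(agg$rank_combined, agg$feature), ]
  structure(agg, class = c("importance_report", class(agg)),
            per_model = per_model)
}

#' Construct a 2x2 confusion matrix from counts
#'
#' @param tp,fn,fp,tn Non-negative integer counts: true/false positives
#'   and negatives for the thyrotoxicosis decision.
#' @return An object of class `confusion_matrix`.
#' @examples
#' confusion_matrix(87, 14, 79, 482)
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be non-negative integers")
  }
  structure(as.list(round(counts)), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("true thyrotoxic", "true non-thyrotoxic"),
                              c("pred thyrotoxic", "pred non-thyrotoxic")))
  print(m)
  invisible(x)
}

#' Count decisions against true labels
#'
#' Tallies the LOOCV decisions into a 2x2 confusion matrix. With
#' `exclude_subclinical = TRUE`, target pairs whose true state is
#' subclinical thyrotoxicosis (normal free T4, suppressed TSH) are dropped
#' before counting -- these are label-negative, so the exclusion can only
#' change the false-positive and true-negative cells, never tp or fn.
#'
#' @param predictions A `loocv_predictions` tibble.
#' @param exclude_subclinical Drop subclinical-thyrotoxicosis targets?
#' @return A `confusion_matrix`.
#' @export
confusion <- function(predictions, exclude_subclinical = FALSE) {
  p <- predictions
  if (exclude_subclinical) {
    p <- p[p$true_state != "subclinical_thyrotoxicosis", , drop = FALSE]
  }
  confusion_matrix(
    tp = sum(p$decision & p$true_label),
    fn = sum(!p$decision & p$true_label),
    fp = sum(p$decision & !p$true_label),
    tn = sum(!p$decision & !p$true_label)
  )
}

#' Diagnostic metrics from a confusion matrix
#'
#' Sensitivity `100*tp/(tp+fn)`, specificity `100*tn/(tn+fp)`, positive
#' predictive value `100*tp/(tp+fp)` and negative predictive value
#' `100*tn/(tn+fn)`, as percentages. A ratio with zero denominator is
#' undefined and reported as `NA`, never 0. Values are kept at full
#' precision; printing rounds to two decimals.
#'
#' @param cm A `confusion_matrix`.
#' @return An object of class `metric_report`: list with `sensitivity`,
#'   `specificity`, `ppv`, `npv` (percent) and the input counts.
#' @examples
#' metrics(confusion_matrix(87, 14, 79, 482))
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  structure(
    list(sensitivity = ratio(cm$tp, cm$tp + cm$fn),
         specificity = ratio(cm$tn, cm$tn + cm$fp),
         ppv = ratio(cm$tp, cm$tp + cm$fp),
         npv = ratio(cm$tn, cm$tn + cm$fn),
         cm = cm),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat(sprintf("sensitivity %s, specificity %s, PPV %s, NPV %s (n = %d)\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv), fmt(x$npv),
              x$cm$tp + x$cm$fn + x$cm$fp + x$cm$tn))
  invisible(x)
}

metric_report_to_row <- function(m) {
  tibble::tibble(tp = m$cm$tp, fn = m$cm$fn, fp = m$cm$fp, tn = m$cm$tn,
                 sensitivity = m$sensitivity, specificity = m$specificity,
                 ppv = m$ppv, npv = m$npv)
}

## Coverage rule adapted to an N-day window: a 10-day rule of >= 3 nights
## cannot be met by a 1-day window, so min_nights is capped at N and
## min_samples prorated at 100 per allowed night (capped at the base rule).
sweep_coverage <- function(base, n_days) {
  coverage_rule(min_nights = min(base$min_nights, n_days),
                min_samples = min(base$min_samples,
                                  100L * min(base$min_nights, n_days)))
}

#' Sweep the heart-rate window length
#'
#' Re-runs the LOOCV evaluation for each window length N. In mode
#' `"joint"` both training and test windows are rebuilt at N days; in mode
#' `"fixed_train_10"` the training pool is built once at 10 days and only
#' the test cases' windows vary with N. At N = 10 both modes coincide with
#' the headline run. The minimum-coverage rule is adapted to short windows
#' (at most N nights can exist in an N-day window); the adapted rule is
#' recorded per row.
#'
#' @param tfts,nights Cohort inputs as for [build_dataset()].
#' @param day_lengths Integer vector of window lengths, within 1..30.
#' @param mode `"joint"` or `"fixed_train_10"`.
#' @param config,threshold,seed Passed to [loocv_predict()].
#' @param step_days Augmentation grid, see [augment_dataset()].
#' @param coverage Base coverage rule (adapted per N).
#' @param tsh_floor,ranges,include_anchor_morning As in [build_dataset()].
#' @return A tibble with one row per window length: `mode`, `n_days`,
#'   `n_targets`, the four confusion counts and the four metrics.
#' @export
window_sweep <- function(tfts, nights, day_lengths = 1:15,
                         mode = c("joint", "fixed_train_10"),
                         config = model_config(), threshold = 0.5,
                         seed = 1L, step_days = 7L,
                         coverage = coverage_rule(), tsh_floor = 0.025,
                         ranges = reference_ranges(),
                         include_anchor_morning = FALSE) {
  mode <- match.arg(mode)
  day_lengths <- as.integer(day_lengths)
  if (any(day_lengths < 1 | day_lengths > 30)) {
    abort("day_lengths must lie in 1..30")
  }
  rows <- list()
  if (mode == "joint") {
    for (n_days in day_lengths) {
      ds <- build_dataset(tfts, nights, n_days = n_days,
                          coverage = sweep_coverage(coverage, n_days),
                          tsh_floor = tsh_floor, ranges = ranges,
                          include_anchor_morning = include_anchor_morning)
      ds <- augment_dataset(ds, step_days = step_days)
      preds <- loocv_predict(ds, config = config, threshold = threshold,
                             seed = seed)
      m <- metrics(confusion(preds))
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(mode = mode, n_days = n_days, n_targets = nrow(preds)),
        metric_report_to_row(m))
    }
  } else {
    ds10 <- build_dataset(tfts, nights, n_days = 10L, coverage = coverage,
                          tsh_floor = tsh_floor, ranges = ranges,
                          include_anchor_morning = include_anchor_morning)
    ds10 <- augment_dataset(ds10, step_days = step_days)
    for (n_days in day_lengths) {
      preds <- fixed_train_predict(ds10, tfts, nights, n_days,
                                   sweep_coverage(coverage, n_days),
                                   config, threshold, seed, tsh_floor,
                                   ranges, include_anchor_morning)
      m <- metrics(confusion(preds))
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(mode = mode, n_days = n_days, n_targets = nrow(preds)),
        metric_report_to_row(m))
    }
  }
  dplyr::bind_rows(rows)
}

## Fixed-training sweep arm: training pool from the 10-day dataset, test
## case features recomputed from N-day windows. Exclusions are keyed by
## (patient, date), which is window-length independent.
fixed_train_predict <- function(ds10, tfts, nights, n_days, coverage_n,
                                config, threshold, seed, tsh_floor, ranges,
                                include_anchor_morning) {
  pairs_n <- build_pairs(tfts, nights, n_days = n_days, coverage = coverage_n,
                         include_anchor_morning = include_anchor_morning)
  cases_n <- enumerate_cases(pairs_n, include_interpolated = FALSE,
                             tsh_floor = tsh_floor, ranges = ranges)
  obs_n <- pairs_n[pairs_n$usable, , drop = FALSE]
  counts <- table(obs_n$patient_id)
  targets <- obs_n[obs_n$patient_id %in% names(counts)[counts >= 2], , drop = FALSE]
  cases10 <- ds10$cases
  rows <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    pid <- targets$patient_id[i]
    tdate <- targets$test_date[i]
    involves_target <- cases10$patient_id == pid &
      (cases10$ref_date == tdate | cases10$tgt_date == tdate)
    train <- cases10[!involves_target, , drop = FALSE]
    test <- cases_n[cases_n$patient_id == pid & cases_n$tgt_date == tdate, ,
                    drop = FALSE]
    if (length(unique(train$label)) < 2) {
      probs <- rep(mean(train$label), nrow(test))
    } else {
      model <- fit_classifier(train, config = config, seed = seed,
                              warn_small = FALSE)
      probs <- predict_proba(model, test)
    }
    avg <- mean(probs)
    rows[[i]] <- tibble::tibble(
      patient_id = pid, target_date = tdate,
      free_t4 = targets$free_t4[i], tsh = targets$tsh[i],
      n_referred = nrow(test), referred_probs = list(probs),
      averaged_probability = avg, decision = avg >= threshold)
  }
  out <- dplyr::bind_rows(rows)
  out$true_label <- is_thyrotoxic(out$free_t4, ranges)
  out$true_state <- classify_state(out$free_t4, out$tsh, ranges)
  class(out) <- c("loocv_predictions", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' Two-group comparison of a clinical variable
#'
#' Compares a continuous or binary variable between two groups the way
#' clinical tables report it: normal-shaped variables as mean +/- SD with
#' Student's t test, non-normal ones as median (IQR) with the Wilcoxon
#' rank-sum test, and binary variables as proportions with the chi-square
#' test. `type = "auto"` decides by Shapiro-Wilk normality (both groups,
#' alpha 0.05); pass an explicit type to override.
#'
#' @param x The variable (numeric, or logical for proportions).
#' @param group A two-level grouping vector aligned with `x`.
#' @param type `"auto"`, `"normal"`, `"nonnormal"` or `"proportion"`.
#' @return A one-row tibble: group labels and sizes, per-group summaries,
#'   test name, statistic and `p_value`.
#' @export
compare_groups <- function(x, group,
                           type = c("auto", "normal", "nonnormal", "proportion")) {
  type <- match.arg(type)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) abort("exactly two groups are required")
  group <- droplevels(group)
  lv <- levels(group)
  x1 <- x[group == lv[1]]
  x2 <- x[group == lv[2]]
  if (length(x1) < 2 || length(x2) < 2) {
    abort("insufficient data: both groups need at least 2 observations")
  }
  if (is.logical(x)) type <- "proportion"
  if (type == "proportion") {
    tab <- table(group, factor(x, levels = c(FALSE, TRUE)))
    ht <- suppressWarnings(chisq.test(tab))
    summ <- function(v) sprintf("%d/%d (%.0f%%)", sum(v), length(v),
                                100 * mean(v))
    return(tibble::tibble(
      group1 = lv[1], group2 = lv[2], n1 = length(x1), n2 = length(x2),
      summary1 = summ(x1), summary2 = summ(x2),
      test = "chi-square", statistic = unname(ht$statistic),
      p_value = ht$p.value))
  }
  if (type == "auto") {
    is_normal <- function(v) {
      if (length(v) < 3 || length(v) > 5000 || var(v) == 0) return(FALSE)
      shapiro.test(v)$p.value > 0.05
    }
    type <- if (is_normal(x1) && is_normal(x2)) "normal" else "nonnormal"
  }
  if (type == "normal") {
    ht <- t.test(x1, x2, var.equal = TRUE)
    summ <- function(v) sprintf("%.3f +/- %.3f", mean(v), sd(v))
    test <- "Student t"
  } else {
    ht <- suppressWarnings(wilcox.test(x1, x2))
    summ <- function(v) sprintf("%.3f (%.3f)", median(v), IQR(v))
    test <- "Wilcoxon rank-sum"
  }
  tibble::tibble(
    group1 = lv[1], group2 = lv[2], n1 = length(x1), n2 = length(x2),
    summary1 = summ(x1), summary2 = summ(x2),
    test = test, statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Compare decision groups among label-negative targets
#'
#' Among targets with normal-or-low free T4 (true label negative), compares
#' the false-positive group (decided thyrotoxic) with the true-negative
#' group on free T4, TSH, and the proportion with TSH < 0.1 mIU/L -- the
#' pattern expected if positive decisions concentrate on the more severe,
#' TSH-suppressed end of the non-thyrotoxic spectrum.
#'
#' @param predictions A `loocv_predictions` tibble.
#' @return A tibble with one row per comparison (`free_t4`, `tsh`,
#'   `tsh_below_0.1`).
#' @export
decision_group_comparison <- function(predictions) {
  p <- predictions[!predictions$true_label, , drop = FALSE]
  grp <- ifelse(p$decision, "decided_thyrotoxic", "decided_non_thyrotoxic")
  dplyr::bind_rows(
    dplyr::mutate(compare_groups(p$free_t4, grp), variable = "free_t4",
                  .before = 1),
    dplyr::mutate(compare_groups(p$tsh, grp), variable = "tsh", .before = 1),
    dplyr::mutate(compare_groups(p$tsh < 0.1, grp),
                  variable = "tsh_below_0.1", .before = 1)
  )
}
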