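#' Empirical quantile transform to the uniform distribution
#'
#' Fits, per feature, the monotone map sending a value to its mid-rank
#' empirical quantile, `(count below + count equal / 2) / n`, with linear
#' interpolation between distinct training values and clamping outside the
#' training range. Applied to the training data itself the transformed
#' marginals are uniform on (0, 1); new values land wherever they fall in
#' the training distribution. The mid-rank form makes the map exactly
#' invariant to uniform duplication of the training set. Fitting must use
#' training cases only -- in cross-validation the transform is refit inside
#' every fold so no information about held-out cases leaks in.
#'
#' @param x A numeric matrix or data frame of training feature columns.
#' @return An object of class `quantile_transform`.
#' @export
quantile_transform <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) abort("features must be numeric")
  maps <- lapply(seq_len(ncol(x)), function(j) {
    v <- sort(x[, j])
    n <- length(v)
    r <- rle(v)
    u <- r$values
    cnt <- r$lengths
    below <- cumsum(c(0, cnt[-length(cnt)]))
    list(u = u, p = (below + cnt / 2) / n)
  })
  names(maps) <- colnames(x)
  structure(list(maps = maps, features = colnames(x)),
            class = "quantile_transform")
}

#' @export
predict.quantile_transform <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(newdata))) {
    newdata <- newdata[, object$features, drop = FALSE]
  }
  out <- matrix(NA_real_, nrow(newdata), ncol(newdata),
                dimnames = dimnames(newdata))
  for (j in seq_len(ncol(newdata))) {
    map <- object$maps[[j]]
    if (length(map$u) == 1) {
      out[, j] <- 0.5
    } else {
      out[, j] <- approx(map$u, map$p, xout = newdata[, j], rule = 2,
                         ties = "ordered")$y
    }
  }
  out
}

#' Gradient-boosting hyperparameters
#'
#' Settings for the boosted-tree ensemble: leaf-wise growth with at most
#' `max_leaves` leaves per tree, `nrounds` trees at learning rate `eta`,
#' and no row or column subsampling by default so that fits are
#' deterministic and exactly invariant to uniform duplication of the
#' training cases (`min_child_weight` and `reg_lambda` are 0 for the same
#' reason: both interact with the absolute scale of the gradient sums).
#'
#' @param nrounds Number of boosting rounds (trees). The default 100 at
#'   `eta = 0.1` is the conventional gradient-boosting operating point and
#'   keeps full cross-validation runs fast; halving the rate and doubling
#'   the rounds gives indistinguishable accuracy at twice the cost.
#' @param eta Learning rate.
#' @param max_leaves Maximum leaves per tree (leaf-wise growth).
#' @param min_child_weight Minimum hessian sum per leaf.
#' @param reg_lambda L2 regularization on leaf weights.
#' @param subsample,colsample_bytree Row/column subsampling rates.
#' @param max_bin Histogram bins for split finding.
#' @param nthread Threads (1 keeps training bit-reproducible).
#' @return An object of class `model_config`.
#' @export
model_config <- function(nrounds = 100L, eta = 0.1, max_leaves = 31L,
                         min_child_weight = 0, reg_lambda = 0,
                         subsample = 1, colsample_bytree = 1,
                         max_bin = 256L, nthread = 1L) {
  structure(list(nrounds = as.integer(nrounds), eta = eta,
                 max_leaves = as.integer(max_leaves),
                 min_child_weight = min_child_weight,
                 reg_lambda = reg_lambda, subsample = subsample,
                 colsample_bytree = colsample_bytree,
                 max_bin = as.integer(max_bin), nthread = as.integer(nthread)),
            class = "model_config")
}

case_feature_matrix <- function(cases, features = hr_feature_names()) {
  missing <- setdiff(features, names(cases))
  if (length(missing)) {
    abort(paste0("cases are missing feature columns: ",
                 paste(missing, collapse = ", ")))
  }
  m <- as.matrix(as.data.frame(cases)[features])
  storage.mode(m) <- "double"
  m
}

#' Fit the thyrotoxicosis classifier
#'
#' Fits the per-feature quantile transform on the training cases, then a
#' gradient-boosted decision-tree ensemble on the transformed features
#' against the binary thyrotoxicosis label. With a fixed seed,
#' `nthread = 1` and no subsampling, refitting on the same data yields an
#' identical model.
#'
#' @param cases A cases tibble from [enumerate_cases()] (needs the 8
#'   feature columns and `label`).
#' @param config A [model_config()].
#' @param seed Integer seed for the boosting backend.
#' @param features Feature columns to use, default [hr_feature_names()].
#' @param warn_small Warn when fewer than 20 training cases are supplied.
#' @return An object of class `thyro_model`.
#' @export
fit_classifier <- function(cases, config = model_config(), seed = 1L,
                           features = hr_feature_names(),
                           warn_small = TRUE) {
  x <- case_feature_matrix(cases, features)
  y <- cases$label
  if (anyNA(y) || !is.logical(y)) abort("cases$label must be logical, no NAs")
  if (length(unique(y)) < 2) {
    abort("training error: training data contain a single class; both thyrotoxic and non-thyrotoxic cases are required")
  }
  if (warn_small && nrow(x) < 20) {
    warn(sprintf("only %d training cases; the classifier expects at least 20", nrow(x)))
  }
  qt <- quantile_transform(x)
  xt <- predict(qt, x)
  params <- list(
    objective = "binary:logistic",
    eval_metric = "logloss",
    eta = config$eta,
    tree_method = "hist",
    grow_policy = "lossguide",
    max_leaves = config$max_leaves,
    max_depth = 0L,
    min_child_weight = config$min_child_weight,
    lambda = config$reg_lambda,
    subsample = config$subsample,
    colsample_bytree = config$colsample_bytree,
    max_bin = config$max_bin,
    nthread = config$nthread,
    seed = as.integer(seed)
  )
  set.seed(seed)
  booster <- xgboost::xgb.train(
    params = params,
    data = xgboost::xgb.DMatrix(xt, label = as.numeric(y)),
    nrounds = config$nrounds, verbose = 0)
  structure(list(transform = qt, booster = booster, features = features,
                 config = config, seed = as.integer(seed),
                 n_train = nrow(x)),
            class = "thyro_model")
}

#' @export
print.thyro_model <- function(x, ...) {
  cat(sprintf("<thyro_model> %d trees on %d cases, %d features, seed %d\n",
              x$config$nrounds, x$n_train, length(x$features), x$seed))
  invisible(x)
}

#' Predict thyrotoxicosis probability
#'
#' Applies the fitted quantile transform and returns the ensemble's
#' probability of the positive (thyrotoxic) class, in `[0, 1]`.
#'
#' @param model A fitted `thyro_model`.
#' @param newdata A data frame/tibble with the model's feature columns, or
#'   a named numeric vector for a single case.
#' @return Numeric vector of probabilities.
#' @export
predict_proba <- function(model, newdata) {
  if (!inherits(model, "thyro_model")) {
    abort("state error: model is not a fitted thyro_model")
  }
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    newdata <- as.data.frame(as.list(newdata))
  }
  x <- case_feature_matrix(newdata, model$features)
  xt <- predict(model$transform, x)
  as.numeric(predict(model$booster, xgboost::xgb.DMatrix(xt)))
}

## Per-model importance table: gain/split shares plus rank columns.
## Ties (typically unused features at 0) are broken by feature-name order
## so each rank column is a permutation of 1..p.
single_model_importance <- function(model) {
  imp <- xgboost::xgb.importance(model = model$booster)
  features <- model$features
  gain <- setNames(numeric(length(features)), features)
  split <- setNames(numeric(length(features)), features)
  if (!is.null(imp) && nrow(imp) > 0) {
    gain[imp$Feature] <- imp$Gain
    split[imp$Feature] <- imp$Frequency
  }
  rank_of <- function(v) {
    ord <- order(-v, features)
    r <- integer(length(v))
    r[ord] <- seq_along(v)
    r
  }
  rg <- rank_of(gain)
  rs <- rank_of(split)
  tibble::tibble(feature = features, gain = as.numeric(gain),
                 split = as.numeric(split), rank_gain = rg,
                 rank_split = rs, rank_combined = (rg + rs) / 2)
}

#' Feature importance across fitted models
#'
#' Ranks the features of one or several fitted models by gain (relative
#' loss-reduction contribution) and by split (relative count of times the
#' feature occurs in a tree), then averages the ranks across models. The
#' combined criterion is the per-model mean of the gain rank and the split
#' rank. Per model, each rank column is a permutation of 1..8 (ties at
#' zero importance broken by feature name).
#'
#' @param models A `thyro_model` or a list of them.
#' @return An object of class `importance_report`: tibble with mean `gain`
#'   and `split` shares and average ranks `rank_gain`, `rank_split`,
#'   `rank_combined`, ordered by the combined rank; per-model tables in
#'   attribute `per_model`.
#' @export
feature_importance <- function(models) {
  if (inherits(models, "thyro_model")) models <- list(models)
  if (!length(models)) abort("at least one fitted model is required")
  per_model <- lapply(models, single_model_importance)
  agg <- per_model[[1]][, "feature", drop = FALSE]
  for (col in c("gain", "split", "rank_gain", "rank_split", "rank_combined")) {
    agg[[col]] <- rowMeans(vapply(per_model, `[[`, numeric(nrow(agg)), col))
  }
  agg <- agg[order(agg$rank_combined, agg$feature), ]
  structure(agg, class = c("importance_report", class(agg)),
            per_model = per_model)
}

#' Write an importance report to CSV
#'
#' @param report An `importance_report` from [feature_importance()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_importance_csv <- function(report, path) {
  readr::write_csv(tibble::as_tibble(report), path)
  invisible(path)
}
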