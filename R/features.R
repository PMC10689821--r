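#' Distribution moments of a sleep heart-rate window
#'
#' Computes the four moment summaries of a pooled heart-rate sample vector:
#' arithmetic mean (bpm), relative standard deviation (population SD
#' divided by mean, dimensionless), skewness (biased Fisher-Pearson third
#' standardized moment) and excess kurtosis (biased fourth standardized
#' moment minus 3). Population (biased) estimators are used throughout for
#' determinism; for the window sizes involved (hundreds to thousands of
#' samples) the bias is negligible. A zero-variance window returns
#' skewness and kurtosis of 0 so constant series remain usable.
#'
#' @param samples Numeric vector of heart-rate values, length >= 2.
#' @return Named numeric vector `c(mean, rsd, skew, kurt)`.
#' @examples
#' compute_moments(c(50, 60, 70))
#' @export
compute_moments <- function(samples) {
  if (!is.numeric(samples) || length(samples) < 2) {
    abort("insufficient data: at least 2 samples are required for moments")
  }
  m <- mean(samples)
  d <- samples - m
  v <- mean(d^2)
  if (v == 0) {
    return(c(mean = m, rsd = 0, skew = 0, kurt = 0))
  }
  c(mean = m,
    rsd = sqrt(v) / m,
    skew = mean(d^3) / v^1.5,
    kurt = mean(d^4) / v^2 - 3)
}

#' Histogram of heart-rate samples on a shared integer grid
#'
#' Discretizes samples into 1-bpm-wide bins covering `shared_range`
#' (rounded outward to integers). Bins are half-open `[edge, edge + 1)`
#' with the final bin closed, so a sample exactly at the upper limit is
#' counted. Two windows compared by [js_divergence()] must be built on the
#' same range so their bin edges are identical; 1 bpm matches the
#' resolution of wearable heart-rate output.
#'
#' @param samples Numeric vector, non-empty, all within `shared_range`.
#' @param shared_range Length-2 numeric `(low, high)` spanning both windows
#'   under comparison.
#' @return An object of class `hr_histogram`: list with integer `bin_edges`
#'   (length bins + 1) and `probabilities` summing to 1.
#' @examples
#' build_histogram(c(60, 60, 61), c(60, 62))
#' @export
build_histogram <- function(samples, shared_range) {
  if (length(samples) < 1) abort("insufficient data: empty sample vector")
  lo <- floor(shared_range[1])
  hi <- ceiling(shared_range[2])
  if (hi <= lo) hi <- lo + 1
  if (any(samples < lo | samples > hi)) {
    abort("samples fall outside shared_range")
  }
  nbins <- hi - lo
  idx <- pmin(floor(samples) - lo + 1, nbins) # top edge folds into closed last bin
  counts <- tabulate(idx, nbins)
  structure(list(bin_edges = lo:hi, probabilities = counts / length(samples)),
            class = "hr_histogram")
}

#' Jensen-Shannon divergence between two heart-rate histograms
#'
#' JSD(p, q) = KL(p || m)/2 + KL(q || m)/2 with m = (p + q)/2, using the
#' 0 log 0 = 0 convention. In natural log units the result is bounded by
#' log(2) ~ 0.6931, attained for distributions with disjoint support, and
#' is 0 iff p = q. The divergence is symmetric in its arguments. Base-2
#' units (bounded by 1) are available via `base = "bits"`.
#'
#' @param p,q `hr_histogram` objects with identical bin edges, or bare
#'   probability vectors of equal length.
#' @param base `"nats"` (natural log, default) or `"bits"`.
#' @return A single non-negative number.
#' @examples
#' js_divergence(c(0.5, 0.5), c(0.9, 0.1))
#' @export
js_divergence <- function(p, q, base = c("nats", "bits")) {
  base <- match.arg(base)
  if (inherits(p, "hr_histogram") || inherits(q, "hr_histogram")) {
    if (!inherits(p, "hr_histogram") || !inherits(q, "hr_histogram")) {
      abort("p and q must both be histograms or both probability vectors")
    }
    if (!identical(p$bin_edges, q$bin_edges)) {
      abort("histograms have mismatched bin edges")
    }
    p <- p$probabilities
    q <- q$probabilities
  }
  if (length(p) != length(q)) abort("probability vectors differ in length")
  if (any(p < 0) || any(q < 0)) abort("negative probabilities")
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log(a[i] / m[i]))
  }
  d <- (kl(p) + kl(q)) / 2
  d <- min(max(d, 0), log(2)) # clip floating-point spill at the bounds
  if (base == "bits") d / log(2) else d
}

## Shared integer range covering two sample vectors.
shared_hr_range <- function(x, y) {
  r <- range(c(x, y))
  c(floor(r[1]), ceiling(r[2]))
}

## JSD directly from two pooled sample vectors (shared integer grid).
js_from_samples <- function(x, y) {
  r <- shared_hr_range(x, y)
  js_divergence(build_histogram(x, r), build_histogram(y, r))
}

#' Feature vector of a referred pair and a target window
#'
#' Builds the eight model inputs for predicting thyroid state at the
#' target date from a known (referred) HR-TFT pair: the referred test's
#' free T4 and TSH; the change, target minus referred, in each of the four
#' window moments; the Jensen-Shannon divergence between the two windows'
#' heart-rate distributions (on a shared 1-bpm grid); and the derived
#' quotient of the mean-HR change by the referred TSH. TSH values below
#' `tsh_floor` are clamped to it before division -- fully suppressed TSH is
#' reported at the assay floor (0.025 mIU/L), and an unclamped quotient
#' would blow up there.
#'
#' @param referred A usable pair row (one-row tibble or list with
#'   `free_t4`, `tsh`, `samples`) as produced by [build_pairs()].
#' @param target A usable pair row or an `hr_window` for the target date.
#' @param tsh_floor Clamp for the referred TSH in the quotient feature.
#' @return Named numeric vector of length 8 in [hr_feature_names()] order.
#' @export
featurize <- function(referred, target, tsh_floor = 0.025) {
  ref_samples <- get_pooled_samples(referred)
  tgt_samples <- get_pooled_samples(target)
  if (length(ref_samples) < 2 || length(tgt_samples) < 2) {
    abort("insufficient data: both windows need at least 2 samples")
  }
  mr <- compute_moments(ref_samples)
  mt <- compute_moments(tgt_samples)
  ref <- as.list(referred)
  d_mean <- mt[["mean"]] - mr[["mean"]]
  out <- c(
    ft4_ref = ref$free_t4,
    tsh_ref = ref$tsh,
    d_mean = d_mean,
    d_rsd = mt[["rsd"]] - mr[["rsd"]],
    d_skew = mt[["skew"]] - mr[["skew"]],
    d_kurt = mt[["kurt"]] - mr[["kurt"]],
    js_div = js_from_samples(ref_samples, tgt_samples),
    d_mean_over_tsh = d_mean / max(ref$tsh, tsh_floor)
  )
  if (!all(is.finite(out))) abort("non-finite feature value")
  out
}

get_pooled_samples <- function(x) {
  if (inherits(x, "hr_window")) return(x$pooled_samples)
  x <- as.list(x)
  if (!is.null(x$samples)) {
    s <- x$samples
    if (is.list(s)) s <- s[[1]]
    return(s)
  }
  if (!is.null(x$pooled_samples)) return(x$pooled_samples)
  abort("cannot extract pooled samples from object")
}
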