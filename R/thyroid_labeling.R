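#' Laboratory reference ranges for thyroid function tests
#'
#' Defaults are the assay-specific intervals used throughout the package:
#' free T4 0.89--1.78 ng/dL and TSH 0.3--4.0 mIU/L. Both intervals are
#' treated as closed: a value equal to either limit is within range, and the
#' overt states require a strict inequality outside the interval. Other
#' laboratories use different intervals, so all four limits are
#' configurable.
#'
#' @param ft4_low,ft4_high Free T4 reference interval, ng/dL.
#' @param tsh_low,tsh_high TSH reference interval, mIU/L.
#' @return An object of class `reference_ranges`.
#' @examples
#' reference_ranges()
#' @export
reference_ranges <- function(ft4_low = 0.89, ft4_high = 1.78,
                             tsh_low = 0.3, tsh_high = 4.0) {
  if (!is.numeric(ft4_low) || !is.numeric(ft4_high) ||
      !is.numeric(tsh_low) || !is.numeric(tsh_high)) {
    abort("reference range limits must be numeric")
  }
  if (ft4_low >= ft4_high) abort("ft4_low must be < ft4_high")
  if (tsh_low >= tsh_high) abort("tsh_low must be < tsh_high")
  structure(
    list(ft4_low = ft4_low, ft4_high = ft4_high,
         tsh_low = tsh_low, tsh_high = tsh_high),
    class = "reference_ranges"
  )
}

#' @export
print.reference_ranges <- function(x, ...) {
  cat(sprintf("free T4: [%.2f, %.2f] ng/dL; TSH: [%.2f, %.2f] mIU/L\n",
              x$ft4_low, x$ft4_high, x$tsh_low, x$tsh_high))
  invisible(x)
}

#' The five thyroid function states
#'
#' @return Character vector of the state labels, ordered from thyrotoxic to
#'   hypothyroid.
#' @export
thyroid_states <- function() {
  c("overt_thyrotoxicosis", "subclinical_thyrotoxicosis", "euthyroid",
    "subclinical_hypothyroidism", "overt_hypothyroidism")
}

validate_tft_values <- function(free_t4, tsh = NULL) {
  if (!is.numeric(free_t4) || anyNA(free_t4) || any(free_t4 <= 0)) {
    abort("free_t4 must be positive and non-missing")
  }
  if (!is.null(tsh)) {
    if (!is.numeric(tsh) || anyNA(tsh) || any(tsh < 0)) {
      abort("tsh must be non-negative and non-missing")
    }
  }
  invisible(TRUE)
}

#' Classify thyroid function state from free T4 and TSH
#'
#' Maps each (free T4, TSH) pair to exactly one of the five thyroid
#' function states. Free T4 dominates: a value above the reference range is
#' overt thyrotoxicosis and below it overt hypothyroidism, regardless of
#' TSH. With free T4 in range, suppressed TSH (below range) is subclinical
#' thyrotoxicosis, elevated TSH subclinical hypothyroidism, and in-range
#' TSH euthyroid. Reference intervals are closed, so boundary values fall
#' inside them.
#'
#' @param free_t4 Free T4, ng/dL (positive). Vectorised.
#' @param tsh TSH, mIU/L (non-negative). Vectorised, recycled against
#'   `free_t4`.
#' @param ranges A [reference_ranges()] object.
#' @return A factor with levels [thyroid_states()].
#' @examples
#' classify_state(2.51, 0.049) # overt thyrotoxicosis
#' classify_state(1.22, 1.488) # euthyroid
#' @export
classify_state <- function(free_t4, tsh, ranges = reference_ranges()) {
  validate_tft_values(free_t4, tsh)
  n <- max(length(free_t4), length(tsh))
  free_t4 <- rep_len(free_t4, n)
  tsh <- rep_len(tsh, n)
  out <- character(n)
  out[free_t4 > ranges$ft4_high] <- "overt_thyrotoxicosis"
  out[free_t4 < ranges$ft4_low] <- "overt_hypothyroidism"
  mid <- free_t4 >= ranges$ft4_low & free_t4 <= ranges$ft4_high
  out[mid & tsh < ranges$tsh_low] <- "subclinical_thyrotoxicosis"
  out[mid & tsh > ranges$tsh_high] <- "subclinical_hypothyroidism"
  out[mid & tsh >= ranges$tsh_low & tsh <= ranges$tsh_high] <- "euthyroid"
  factor(out, levels = thyroid_states())
}

#' Binary thyrotoxicosis label
#'
#' The label used for all model training and evaluation: `TRUE` iff free T4
#' strictly exceeds the upper reference limit (default > 1.78 ng/dL). TSH
#' plays no role in the label.
#'
#' @inheritParams classify_state
#' @return Logical vector.
#' @examples
#' is_thyrotoxic(c(1.78, 2.51)) # FALSE TRUE
#' @export
is_thyrotoxic <- function(free_t4, ranges = reference_ranges()) {
  validate_tft_values(free_t4)
  free_t4 > ranges$ft4_high
}

#' Read thyroid function test results from CSV
#'
#' Expects columns `patient_id,test_date,free_t4,tsh` with ISO-8601 dates.
#' Values are validated (free T4 positive, TSH non-negative, parseable
#' dates) and offending rows reported by number.
#'
#' @param path Path to a CSV file.
#' @return A tibble with `patient_id` (character), `test_date` (Date),
#'   `free_t4`, `tsh` (numeric).
#' @export
read_tft_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          patient_id = readr::col_character(),
                          test_date = readr::col_date(),
                          free_t4 = readr::col_double(),
                          tsh = readr::col_double()
                        ))
  required <- c("patient_id", "test_date", "free_t4", "tsh")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("TFT CSV is missing columns: ", paste(missing, collapse = ", ")))
  }
  bad <- which(is.na(df$test_date) | is.na(df$free_t4) | is.na(df$tsh) |
                 df$free_t4 <= 0 | df$tsh < 0)
  if (length(bad)) {
    abort(paste0("invalid TFT rows (1-based, excluding header): ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  tibble::as_tibble(df[required])
}
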