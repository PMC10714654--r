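#' Signed percentage error of an estimate
#'
#' `100 * (estimated - actual) / actual`; positive values are
#' overestimation.  Vectorised.
#'
#' @param estimated_g,actual_g Estimated and actual weights in grams;
#'   `actual_g` must be positive.
#' @return Signed percentage error(s).
#' @examples
#' percentage_error(3300, 3000)  # +10
#' @export
percentage_error <- function(estimated_g, actual_g) {
  if (any(actual_g <= 0)) stop("'actual_g' must be positive")
  100 * (estimated_g - actual_g) / actual_g
}

bucket_levels <- c("over_gt15", "over_10_15", "accepted_lt10",
                   "under_10_15", "under_gt15")

#' Bucket signed percentage errors into the standard report ranges
#'
#' Assigns each signed percentage error to one of five ranges:
#' acceptable (`|PE| < 10`), over- or under-estimation by 10--15%, and
#' over- or under-estimation beyond 15%.  Boundary conventions: exactly 10
#' and exactly 15 fall in the 10--15% bucket (the acceptable range is
#' strictly below 10, matching the "< 10%" reporting convention; the
#' extreme range is strictly above 15).
#'
#' @param pe Numeric vector of signed percentage errors (non-empty).
#' @return Data.frame with one row per bucket: `bucket`, `count`,
#'   `percent` (share of cases, rounded to 2 decimals).
#' @examples
#' bucket_errors(c(5, 12, -8, -16))
#' @export
bucket_errors <- function(pe) {
  if (length(pe) == 0) stop("empty percentage-error list")
  ape <- abs(pe)
  bucket <- ifelse(ape < 10, "accepted_lt10",
            ifelse(ape <= 15,
                   ifelse(pe > 0, "over_10_15", "under_10_15"),
                   ifelse(pe > 0, "over_gt15", "under_gt15")))
  counts <- table(factor(bucket, levels = bucket_levels))
  data.frame(bucket = bucket_levels, count = as.integer(counts),
             percent = round(100 * as.integer(counts) / length(pe), 2))
}

#' Percentage-error evaluation report
#'
#' The complete model-evaluation report for a set of estimates against
#' actual weights: per-case signed percentage errors, the mean absolute
#' percentage error (the headline accuracy figure), the signed mean as a
#' bias indicator, the five-range bucket table ([bucket_errors()]) and the
#' share of estimates within the clinically accepted 10% band.
#'
#' @param estimates,actuals Equal-length numeric vectors in grams; actuals
#'   positive.
#' @return An `error_report` list: `pe` (signed, per case), `mpe_abs`,
#'   `mpe_signed`, `buckets`, `accepted_percent`, `n_total`.
#' @examples
#' mpe_report(c(3300, 2800, 3100), c(3000, 3000, 3000))
#' @export
mpe_report <- function(estimates, actuals) {
  if (length(estimates) != length(actuals)) stop("length mismatch")
  if (length(estimates) == 0) stop("empty input")
  pe <- percentage_error(estimates, actuals)
  buckets <- bucket_errors(pe)
  accepted <- buckets$count[buckets$bucket == "accepted_lt10"]
  structure(list(pe = pe, mpe_abs = mean(abs(pe)), mpe_signed = mean(pe),
                 buckets = buckets,
                 accepted_percent = 100 * accepted / length(pe),
                 n_total = length(pe)),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("error_report: n = %d, MPE (abs) = %.2f%%, signed = %+.2f%%\n",
              x$n_total, x$mpe_abs, x$mpe_signed))
  cat(sprintf("  within 10%%: %.2f%% of cases\n", x$accepted_percent))
  print(x$buckets, row.names = FALSE)
  invisible(x)
}
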