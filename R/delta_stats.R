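## Validation statistics: natural-log transform of epitope counts,
## observed-vs-reference deltas, deviation fractions and two-sided
## percentile spreads around the median.

#' Log-delta between observed and reference epitope values
#'
#' Epitope counts are assumed to act on alloreactivity on a natural-log
#' scale, so observed and reference values are compared as
#' `ln(observed) - ln(reference)`; a delta beyond +1 or below -1 (one
#' full log unit) is a high deviation. `ln(0)` is undefined and the zero
#' policy makes the handling explicit: `"exclude"` marks the couple
#' excluded (reported, never silent), `"add_one"` uses `ln(x + 1)` on
#' both values.
#'
#' Vectorized over `observed` and `reference`.
#'
#' @param observed,reference Nonnegative epitope values (the observed
#'   value is typically a frequency-weighted expectation, the reference
#'   the integer score from true genotypes).
#' @param zero_policy `"exclude"` or `"add_one"`.
#' @return A data.frame of class `couple_delta` with columns
#'   `ln_observed`, `ln_reference`, `delta`, `zero_handled`, `excluded`,
#'   `high_deviation`.
#' @export
ln_delta <- function(observed, reference,
                     zero_policy = c("exclude", "add_one")) {
  zero_policy <- match.arg(zero_policy)
  observed <- as.numeric(observed)
  reference <- as.numeric(reference)
  if (any(observed < 0) || any(reference < 0)) {
    stop("epitope values must be nonnegative", call. = FALSE)
  }
  zero <- observed == 0 | reference == 0
  if (zero_policy == "add_one") {
    lo <- log(observed + 1)
    lr <- log(reference + 1)
    excluded <- rep(FALSE, length(observed))
  } else {
    lo <- ifelse(zero, NA_real_, log(observed))
    lr <- ifelse(zero, NA_real_, log(reference))
    excluded <- zero
  }
  delta <- lo - lr
  structure(
    data.frame(ln_observed = lo, ln_reference = lr, delta = delta,
               zero_handled = zero, excluded = excluded,
               high_deviation = !is.na(delta) & abs(delta) > 1),
    class = c("couple_delta", "data.frame"))
}

#' Two-sided percentile spread around the median
#'
#' For a level of, say, 75%, the spread reaches to the delta that 37.5%
#' of the values above the median stretch to and the delta that 37.5% of
#' the values below the median stretch to — i.e. the empirical quantiles
#' at (50 - level/2)% and (50 + level/2)%. Quantiles use linear
#' interpolation between order statistics (R's default type 7), fixed so
#' results are comparable across runs.
#'
#' @param deltas Nonempty numeric vector.
#' @param level Central coverage level in percent (e.g. 50, 75, 95, 99,
#'   99.9).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
percentile_spread <- function(deltas, level) {
  deltas <- deltas[!is.na(deltas)]
  if (length(deltas) == 0L) stop("no deltas to summarize", call. = FALSE)
  if (level <= 0 || level > 100) stop("level must be in (0, 100]", call. = FALSE)
  q <- stats::quantile(deltas, c(0.5 - level / 200, 0.5 + level / 200),
                       type = 7, names = FALSE)
  c(lower = q[[1L]], upper = q[[2L]])
}

#' Summarize a set of couple deltas
#'
#' Computes the fraction of couples with a delta of zero (zero is
#' declared when `|delta|` is below a documented rounding tolerance —
#' exact float equality is meaningless after weighted sums), the
#' fraction within each absolute threshold, counts of high deviations
#' split by sign, and the two-sided percentile spreads at 50, 75, 95, 99
#' and 99.9%.
#'
#' @param deltas Numeric vector of deltas (NAs, e.g. excluded zero-count
#'   couples, are dropped and counted).
#' @param thresholds Absolute-delta thresholds for the `within` fractions.
#' @param zero_tol Rounding tolerance below which a delta counts as zero.
#' @param n_unimputable Number of couples for which no estimate could be
#'   produced (reported alongside).
#' @return A list of class `delta_summary`: `n_total`, `n_used`,
#'   `n_unimputable`, `n_zero_excluded`, `fraction_zero_delta`,
#'   `fraction_within` (named by threshold), `n_high_positive`,
#'   `n_high_negative`, `spreads` (matrix levels x lower/upper),
#'   `quantile_method`.
#' @export
summarize_deltas <- function(deltas, thresholds = c(0, 0.1, 1),
                             zero_tol = 1e-12, n_unimputable = 0L) {
  n_total <- length(deltas) + n_unimputable
  n_zero_excluded <- sum(is.na(deltas))
  d <- deltas[!is.na(deltas)]
  if (length(d) == 0L) stop("no usable deltas", call. = FALSE)
  frac_within <- vapply(thresholds, function(t) {
    mean(abs(d) <= max(t, zero_tol))
  }, numeric(1L))
  names(frac_within) <- as.character(thresholds)
  levels <- c(50, 75, 95, 99, 99.9)
  spreads <- t(vapply(levels, function(l) percentile_spread(d, l),
                      numeric(2L)))
  dimnames(spreads) <- list(as.character(levels), c("lower", "upper"))
  structure(
    list(n_total = n_total, n_used = length(d),
         n_unimputable = n_unimputable,
         n_zero_excluded = n_zero_excluded,
         fraction_zero_delta = mean(abs(d) <= zero_tol),
         fraction_within = frac_within,
         n_high_positive = sum(d > 1),
         n_high_negative = sum(d < -1),
         spreads = spreads,
         quantile_method = "type7_linear_interpolation"),
    class = "delta_summary")
}

#' @export
print.delta_summary <- function(x, ...) {
  cat(sprintf(
    "<delta_summary> n=%d (used %d, unimputable %d, zero-excluded %d)\n",
    x$n_total, x$n_used, x$n_unimputable, x$n_zero_excluded))
  cat(sprintf("  zero-delta fraction: %.3f\n", x$fraction_zero_delta))
  for (t in names(x$fraction_within)) {
    cat(sprintf("  |delta| <= %-4s     : %.3f\n", t, x$fraction_within[[t]]))
  }
  cat(sprintf("  high deviations: %d positive, %d negative\n",
              x$n_high_positive, x$n_high_negative))
  for (l in rownames(x$spreads)) {
    cat(sprintf("  %5s%% spread: [%+.4f, %+.4f]\n", l,
                x$spreads[l, "lower"], x$spreads[l, "upper"]))
  }
  invisible(x)
}
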