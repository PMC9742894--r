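# Standardized central moments shared by the time-series and PSD families.
# Skewness is the population-formula standardized third moment
# m3 / m2^(3/2); kurtosis the non-excess standardized fourth moment
# m4 / m2^2 (a Gaussian sample tends to 3).  SD is the sample SD (n - 1).
# With zero variance, skewness and kurtosis are undefined (NA), never 0.
moment_summary <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L)
    return(c(mean = NA_real_, sd = NA_real_,
             skewness = NA_real_, kurtosis = NA_real_))
  mu <- mean(x)
  s <- if (n >= 2L) stats::sd(x) else NA_real_
  m2 <- mean((x - mu)^2)
  if (n < 3L || m2 == 0) {
    sk <- NA_real_; ku <- NA_real_
  } else {
    sk <- mean((x - mu)^3) / m2^1.5
    ku <- mean((x - mu)^4) / m2^2
  }
  c(mean = mu, sd = s, skewness = sk, kurtosis = ku)
}

#' Distribution moments of an SpO2 trace
#'
#' Mean, sample SD, skewness and non-excess kurtosis of the valid samples.
#'
#' @param signal an `oximetry_signal`.
#' @return named numeric vector `mean, sd, skewness, kurtosis`.
#' @export
distribution_moments <- function(signal) {
  x <- signal$samples[signal$valid]
  if (length(x) == 0L) stop("no valid samples")
  moment_summary(x)
}

#' Median and nadir of an SpO2 trace
#'
#' Median (midpoint interpolation on ties/even n) and minimum of the valid
#' samples, as read off the cumulative distribution.
#'
#' @param signal an `oximetry_signal`.
#' @return named numeric vector `median, nadir`.
#' @export
cumulative_metrics <- function(signal) {
  x <- signal$samples[signal$valid]
  if (length(x) == 0L) stop("no valid samples")
  c(median = stats::median(x), nadir = min(x))
}

#' Percentage of sleep time at or below SpO2 thresholds (TX)
#'
#' For each threshold X, 100 times the fraction of valid sample time with
#' SpO2 <= X (inclusive by default).  The denominator is valid-sample time
#' within the analyzed (stage-restricted) signal, so artifacts inflate
#' neither numerator nor denominator.
#'
#' @param signal an `oximetry_signal` restricted to sleep.
#' @param thresholds %SpO2 thresholds; default 80--94 by 2.
#' @param inclusive use `<=` (default) rather than `<`.
#' @return named numeric vector of %TST, names `T80`, `T82`, ...
#' @export
time_below <- function(signal, thresholds = seq(80, 94, by = 2),
                       inclusive = TRUE) {
  x <- signal$samples[signal$valid]
  if (length(x) == 0L) stop("total sleep time is zero")
  out <- vapply(thresholds, function(th) {
    100 * mean(if (inclusive) x <= th else x < th)
  }, numeric(1))
  names(out) <- paste0("T", thresholds)
  out
}
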