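#' Welch power spectral density of an SpO2 trace
#'
#' Averaged periodogram with Hann taper, 50% overlap and per-segment mean
#' detrending.  Invalid samples are linearly interpolated before the
#' transform (the valid fraction is recorded in the metadata); the
#' estimate is one-sided and normalized as a density, so
#' `sum(power) * df` approximates the detrended signal variance.
#'
#' @param signal a cleaned `oximetry_signal`.
#' @param segment_s segment length in seconds (default 2048).
#' @param overlap fractional segment overlap (default 0.5).
#' @param min_duration_s minimum usable signal duration (default 3600).
#' @return an object of class `psd_estimate` with fields `freqs` (Hz),
#'   `power` ((%SpO2)^2 / Hz) and `meta`.
#' @export
estimate_psd <- function(signal, segment_s = 2048, overlap = 0.5,
                         min_duration_s = 3600) {
  n <- length(signal$samples)
  fs <- signal$rate
  if (n / fs < min_duration_s) stop("signal too short for PSD estimation")
  if (!any(signal$valid)) stop("no valid samples")

  x <- signal$samples
  x[!signal$valid] <- NA_real_
  x <- as.numeric(stats::approx(seq_len(n), x, xout = seq_len(n),
                                rule = 2)$y)

  nseg <- as.integer(round(segment_s * fs))
  nseg <- min(nseg, n)
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nseg - 1) / nseg))   # Hann
  W <- sum(w^2)
  nf <- nseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nf)])^2 / (fs * W)
    sp[c(-1L, -nf)] <- 2 * sp[c(-1L, -nf)]   # one-sided doubling
    acc <- acc + sp
  }
  power <- acc / length(starts)
  freqs <- (seq_len(nf) - 1L) * fs / nseg
  structure(list(freqs = freqs, power = power,
                 meta = list(segment_s = nseg / fs, overlap = overlap,
                             taper = "hann", n_segments = length(starts),
                             valid_fraction = mean(signal$valid))),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf(
    "<psd_estimate> %d bins to %.4g Hz (%d x %gs Hann segments, %.0f%% valid)\n",
    length(x$freqs), max(x$freqs), x$meta$n_segments, x$meta$segment_s,
    100 * x$meta$valid_fraction))
  invisible(x)
}

#' Band moments and spectral entropy of a PSD
#'
#' Treats the in-band bin powers as a sample and computes their mean, SD,
#' skewness and non-excess kurtosis, plus the spectral entropy
#' `-sum(p_i log p_i)` with `p_i` the in-band powers normalized to sum 1
#' (natural log by default, so a flat band of N bins gives `log(N)` and a
#' single-bin band gives 0).
#'
#' @param psd a `psd_estimate`.
#' @param band numeric length-2, `c(f_lo, f_hi)` in Hz (inclusive).
#' @param log_base base of the entropy logarithm (default `exp(1)`).
#' @return named numeric vector
#'   `mean, sd, skewness, kurtosis, spectral_entropy`.
#' @export
band_features <- function(psd, band, log_base = exp(1)) {
  if (length(band) != 2L || band[2] <= band[1]) stop("invalid band")
  if (band[1] < min(psd$freqs) - 1e-12 || band[2] > max(psd$freqs) + 1e-12)
    stop("band outside PSD range")
  idx <- psd$freqs >= band[1] - 1e-12 & psd$freqs <= band[2] + 1e-12
  p <- psd$power[idx]
  if (length(p) < 3L) stop("fewer than 3 bins in band")
  mom <- moment_summary(p)
  tot <- sum(p)
  ent <- if (tot > 0) {
    q <- p[p > 0] / tot
    -sum(q * log(q)) / log(log_base)
  } else NA_real_
  c(mom, spectral_entropy = ent)
}
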