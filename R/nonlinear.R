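#' Sample entropy of a resampled SpO2 trace
#'
#' `SampEn = -log(A/B)` where `B` counts pairs of length-`m` templates
#' within Chebyshev distance `tol` and `A` the same for length-`m+1`
#' templates; self-matches are excluded.  With the default `r_mode =
#' "sd"`, the tolerance is `r` times the SD of the valid samples (the
#' convention in the oximetry-entropy literature); `r_mode = "absolute"`
#' uses `r` in %SpO2 directly.  Templates containing invalid samples are
#' excluded from both counts.
#'
#' @param signal an `oximetry_signal`, typically resampled to 0.2 Hz with
#'   [resample_signal()].
#' @param m template length (default 1).
#' @param r tolerance parameter (default 0.25).
#' @param r_mode `"sd"` (tolerance `r * SD`) or `"absolute"`.
#' @return sample entropy (>= 0), or `NA` with a warning when no template
#'   pair matches.
#' @export
sample_entropy <- function(signal, m = 1, r = 0.25,
                           r_mode = c("sd", "absolute")) {
  r_mode <- match.arg(r_mode)
  if (r <= 0) stop("r must be positive")
  x <- signal$samples
  x[!signal$valid] <- NA_real_
  nv <- sum(signal$valid)
  if (nv < m + 2L) stop("too few valid samples")
  tol <- if (r_mode == "sd") {
    s <- stats::sd(x, na.rm = TRUE)
    if (s == 0) 0 else r * s
  } else r
  # both counts range over the first n - m template positions, so a
  # perfectly regular sequence gives A = B and an entropy of exactly 0
  n_templates <- length(x) - m
  B <- count_template_pairs(x, m, tol, n_templates)
  A <- count_template_pairs(x, m + 1L, tol, n_templates)
  if (B == 0 || A == 0) {
    warning("no matching templates; sample entropy undefined")
    return(NA_real_)
  }
  -log(A / B)
}

# Pairs (i < j) of length-k templates within Chebyshev distance tol,
# over the first n_templates starting positions.
# Vectorized over template lag; NA comparisons (invalid samples) drop out.
count_template_pairs <- function(x, k, tol, n_templates = NULL) {
  n <- length(x)
  N <- if (is.null(n_templates)) n - k + 1L else
    min(n_templates, n - k + 1L)
  if (N < 2L) return(0)
  total <- 0
  for (d in seq_len(N - 1L)) {
    m1 <- N - d
    cheb <- abs(x[seq_len(m1)] - x[d + seq_len(m1)])
    if (k > 1L) for (l in seq_len(k - 1L))
      cheb <- pmax(cheb, abs(x[l + seq_len(m1)] - x[d + l + seq_len(m1)]))
    total <- total + sum(cheb <= tol, na.rm = TRUE)
  }
  total
}

#' Central tendency measure (CTM)
#'
#' From the Poincare plot of the first difference of the trace, the
#' proportion of points `(d_i, d_{i+1})` (with `d_i = x_{i+1} - x_i`)
#' whose Euclidean norm is strictly less than the radius `rho`.  Lower
#' values indicate a more variable signal.
#'
#' @param signal an `oximetry_signal`, typically resampled to 0.2 Hz.
#' @param rho radius in %SpO2 (default 1).
#' @return proportion in `[0, 1]`.
#' @export
central_tendency_measure <- function(signal, rho = 1) {
  if (rho <= 0) stop("rho must be positive")
  x <- signal$samples
  x[!signal$valid] <- NA_real_
  if (sum(signal$valid) < 3L) stop("too few valid samples")
  d <- diff(x)
  d1 <- d[-length(d)]
  d2 <- d[-1L]
  ok <- !is.na(d1) & !is.na(d2)
  if (!any(ok)) stop("no Poincare points")
  mean(sqrt(d1[ok]^2 + d2[ok]^2) < rho)
}
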