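# Independent brute-force reference implementations used as oracles.
# These deliberately use the naive O(n^2) / two-pass formulations and do
# not share code with the package internals.

# template counts follow the standard convention: both lengths range
# over the first n - m starting positions
brute_sampen <- function(x, m, tol) {
  count_k <- function(k) {
    N <- length(x) - m
    total <- 0L
    for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
      d <- max(abs(x[i:(i + k - 1L)] - x[j:(j + k - 1L)]))
      if (!is.na(d) && d <= tol) total <- total + 1L
    }
    total
  }
  B <- count_k(m)
  A <- count_k(m + 1L)
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

brute_ctm <- function(x, rho) {
  d <- diff(x)
  cnt <- 0L; tot <- 0L
  for (i in seq_len(length(d) - 1L)) {
    tot <- tot + 1L
    if (sqrt(d[i]^2 + d[i + 1L]^2) < rho) cnt <- cnt + 1L
  }
  cnt / tot
}

brute_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  c(mean = mu, sd = sqrt(sum((x - mu)^2) / (n - 1)),
    skewness = m3 / m2^1.5, kurtosis = m4 / m2^2)
}

# BH step-up: find largest i with p_(i) <= q i / m; reject 1..i
brute_bh_flags <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= q * seq_len(m) / m)
  flags <- rep(FALSE, m)
  if (length(below)) flags[o[seq_len(max(below))]] <- TRUE
  flags
}

# Cox partial likelihood (no ties) for an arbitrary design matrix
brute_cox_beta <- function(time, event, X) {
  negpl <- function(b) {
    lp <- as.numeric(X %*% b)
    s <- 0
    for (i in which(event)) {
      risk <- time >= time[i]
      s <- s - (lp[i] - log(sum(exp(lp[risk]))))
    }
    s
  }
  stats::optim(rep(0, ncol(X)), negpl, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))$par
}

# constant-baseline flat signal helpers
flat_signal <- function(value, n, rate = 1) clean_signal(rep(value, n), rate)

sleep_hypnogram <- function(hours, epoch_s = 30, stage = "N2")
  hypnogram(rep(stage, round(hours * 3600 / epoch_s)), epoch_s)

# rectangular-dip night: baseline with square desaturations at given times
square_dip_signal <- function(baseline, depth, dip_starts, dip_len_s,
                              total_s, rate = 1) {
  x <- rep(baseline, total_s * rate)
  for (s in dip_starts) {
    idx <- (round(s * rate):(round((s + dip_len_s) * rate) - 1L)) + 1L
    x[idx] <- baseline - depth
  }
  clean_signal(x, rate)
}
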