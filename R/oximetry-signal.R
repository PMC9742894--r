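#' Construct an oximetry signal object
#'
#' Container for a sampled nocturnal SpO2 trace.  Samples are percentages
#' (0--100); `valid` marks samples usable for analysis (artifact-free),
#' aligned with `samples`.
#'
#' @param samples numeric vector of %SpO2 values.
#' @param rate sampling rate in Hz (> 0).
#' @param valid logical vector, same length as `samples`.  Defaults to all
#'   `TRUE`.
#' @param start_time recording start offset in seconds.
#' @return an object of class `oximetry_signal`.
#' @export
oximetry_signal <- function(samples, rate, valid = NULL, start_time = 0) {
  if (length(samples) == 0L) stop("empty signal")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number")
  if (is.null(valid)) valid <- !is.na(samples)
  if (length(valid) != length(samples))
    stop("samples and valid must have equal length")
  structure(
    list(samples = as.numeric(samples), rate = as.numeric(rate),
         valid = as.logical(valid) & !is.na(samples),
         start_time = as.numeric(start_time)),
    class = "oximetry_signal")
}

#' @export
print.oximetry_signal <- function(x, ...) {
  cat(sprintf("<oximetry_signal> %d samples at %g Hz (%.2f h), %.1f%% valid\n",
              length(x$samples), x$rate,
              length(x$samples) / x$rate / 3600,
              100 * mean(x$valid)))
  invisible(x)
}

#' Duration of a signal in seconds
#' @param signal an `oximetry_signal`.
#' @return duration in seconds.
#' @export
signal_duration_s <- function(signal) length(signal$samples) / signal$rate

#' Clean a raw SpO2 trace
#'
#' Marks physiologically impossible samples (outside `[floor_pct, 100]`,
#' which includes oximeter dropout zeros) as invalid, then bridges short
#' invalid runs by linear interpolation.  Runs longer than `max_gap_s`
#' stay invalid and are excluded from every downstream statistic.
#'
#' @param raw numeric vector of raw %SpO2 samples.
#' @param rate sampling rate in Hz.
#' @param max_gap_s longest artifact run (seconds) bridged by
#'   interpolation; default 30.
#' @param floor_pct physiologic floor in %SpO2; default 50.
#' @param start_time seconds from recording start.
#' @return a cleaned `oximetry_signal`.
#' @export
clean_signal <- function(raw, rate, max_gap_s = 30, floor_pct = 50,
                         start_time = 0) {
  if (length(raw) == 0L) stop("empty signal")
  if (rate <= 0) stop("rate must be positive")
  x <- as.numeric(raw)
  valid <- !is.na(x) & x >= floor_pct & x <= 100
  if (!any(valid)) stop("no valid samples")
  x[!valid] <- NA_real_

  # bridge interior invalid runs no longer than max_gap_s
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  max_run <- max_gap_s * rate
  for (k in seq_along(r$lengths)) {
    if (r$values[k]) next
    if (r$lengths[k] > max_run) next
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 == 1L || i1 == length(x)) next   # edge runs cannot be bridged
    a <- x[i0 - 1L]; b <- x[i1 + 1L]
    w <- seq_len(r$lengths[k]) / (r$lengths[k] + 1L)
    x[i0:i1] <- a + (b - a) * w
    valid[i0:i1] <- TRUE
  }
  oximetry_signal(x, rate, valid, start_time)
}

#' Resample a signal by block averaging
#'
#' Each output sample is the mean of the valid input samples in its
#' `1/target_rate` window; windows with no valid samples are invalid.
#' Block averaging (rather than decimation) suppresses measurement noise.
#'
#' @param signal an `oximetry_signal`.
#' @param target_rate output rate in Hz; must not exceed `signal$rate`.
#' @return an `oximetry_signal` at `target_rate`.
#' @export
resample_signal <- function(signal, target_rate) {
  if (target_rate <= 0) stop("target_rate must be positive")
  if (target_rate > signal$rate)
    stop("target_rate must not exceed the signal rate")
  block <- signal$rate / target_rate
  if (abs(block - round(block)) > 1e-8)
    stop("signal rate must be an integer multiple of target_rate")
  block <- as.integer(round(block))
  if (block == 1L) return(signal)
  n <- length(signal$samples)
  nb <- n %/% block
  if (nb == 0L) stop("signal shorter than one resampling window")
  idx <- rep(seq_len(nb), each = block)
  x <- signal$samples[seq_len(nb * block)]
  v <- signal$valid[seq_len(nb * block)]
  x[!v] <- NA_real_
  sums <- rowsum(ifelse(is.na(x), 0, x), idx)
  cnts <- rowsum(as.numeric(!is.na(x)), idx)
  out <- as.numeric(sums / cnts)          # NaN where no valid sample
  valid <- cnts[, 1L] > 0
  out[!valid] <- NA_real_
  oximetry_signal(out, target_rate, valid, signal$start_time)
}

# ---- hypnogram ------------------------------------------------------------

.STAGES <- c("WAKE", "N1", "N2", "N3", "REM")

#' Construct a hypnogram
#'
#' Epoch-coded sleep stages at a fixed epoch length.
#'
#' @param stages character vector of stage codes among
#'   `WAKE, N1, N2, N3, REM`.
#' @param epoch_s epoch length in seconds (default 30).
#' @return an object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_s = 30) {
  if (epoch_s <= 0) stop("epoch_s must be positive")
  stages <- toupper(as.character(stages))
  bad <- setdiff(unique(stages), .STAGES)
  if (length(bad))
    stop("unknown stage code(s): ", paste(bad, collapse = ", "))
  structure(list(stages = stages, epoch_s = as.numeric(epoch_s)),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d x %gs epochs, TST %.2f h\n",
              length(x$stages), x$epoch_s, tst_hours(x)))
  invisible(x)
}

#' Expand a stage selector to canonical stage codes
#'
#' `"NREM"` expands to `N1, N2, N3`; `"total"` (or `"sleep"`) to all
#' non-wake stages; canonical codes pass through.
#'
#' @param stages character vector of selectors.
#' @return character vector of canonical stage codes.
#' @export
expand_stages <- function(stages) {
  if (length(stages) == 0L) stop("empty stage set")
  out <- unlist(lapply(toupper(stages), function(s) {
    switch(s,
           NREM = c("N1", "N2", "N3"),
           TOTAL = , SLEEP = c("N1", "N2", "N3", "REM"),
           s)
  }))
  bad <- setdiff(out, .STAGES)
  if (length(bad))
    stop("unknown stage code(s): ", paste(bad, collapse = ", "))
  unique(out)
}

#' Total sleep time in hours
#'
#' Time spent in the selected stages (default: all non-wake stages).
#'
#' @param hyp a `hypnogram`.
#' @param stages stage selector (see [expand_stages()]).
#' @return hours.
#' @export
tst_hours <- function(hyp, stages = "sleep") {
  st <- expand_stages(stages)
  sum(hyp$stages %in% st) * hyp$epoch_s / 3600
}

#' Restrict a signal to selected sleep stages
#'
#' Samples falling in epochs outside the stage set are marked invalid, so
#' every downstream statistic is computed over the selected stages only.
#' Per-hour rates must then use [tst_hours()] over the same stage set.
#'
#' @param signal an `oximetry_signal`.
#' @param hyp a `hypnogram` covering the signal duration.
#' @param stages stage selector (see [expand_stages()]).
#' @return an `oximetry_signal` with out-of-stage samples invalidated.
#' @export
restrict_to_stage <- function(signal, hyp, stages) {
  st <- expand_stages(stages)
  n <- length(signal$samples)
  t_s <- (seq_len(n) - 1L) / signal$rate
  epoch <- pmin(floor(t_s / hyp$epoch_s) + 1L, length(hyp$stages))
  keep <- hyp$stages[epoch] %in% st
  valid <- signal$valid & keep
  x <- signal$samples
  x[!valid] <- NA_real_
  oximetry_signal(x, signal$rate, valid, signal$start_time)
}

# ---- respiratory events ----------------------------------------------------

.EVENT_KINDS <- c("obstructive-apnea", "central-apnea", "hypopnea")

#' Construct a respiratory event table
#'
#' Events are sorted by onset and overlapping intervals are merged
#' (half-open convention `[onset, onset + duration)`); a merged event keeps
#' the kind of the earliest contributor.
#'
#' @param onset numeric vector, seconds from recording start.
#' @param duration numeric vector, seconds (> 0).
#' @param kind character vector among
#'   `obstructive-apnea, central-apnea, hypopnea`.
#' @return a `data.frame` with columns `onset`, `duration`, `kind`.
#' @export
respiratory_events <- function(onset, duration, kind = "hypopnea") {
  if (length(onset) == 0L)
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      kind = character(0)))
  if (any(duration <= 0)) stop("event duration must be positive")
  kind <- rep_len(as.character(kind), length(onset))
  bad <- setdiff(unique(kind), .EVENT_KINDS)
  if (length(bad)) stop("unknown event kind(s): ", paste(bad, collapse = ", "))
  o <- order(onset)
  onset <- onset[o]; duration <- duration[o]; kind <- kind[o]
  # merge overlaps
  out_on <- onset[1]; out_end <- onset[1] + duration[1]; out_kind <- kind[1]
  for (i in seq_along(onset)[-1]) {
    if (onset[i] < out_end[length(out_end)]) {
      out_end[length(out_end)] <-
        max(out_end[length(out_end)], onset[i] + duration[i])
    } else {
      out_on <- c(out_on, onset[i])
      out_end <- c(out_end, onset[i] + duration[i])
      out_kind <- c(out_kind, kind[i])
    }
  }
  data.frame(onset = out_on, duration = out_end - out_on, kind = out_kind,
             stringsAsFactors = FALSE)
}

# ---- plain-text readers ----------------------------------------------------

#' Read an SpO2 trace from CSV
#'
#' Expects columns `time_s` and `spo2`; the sampling rate is inferred from
#' the median time step.  The trace is passed through [clean_signal()].
#'
#' @param path CSV file path.
#' @param ... passed to [clean_signal()].
#' @return a cleaned `oximetry_signal`.
#' @export
read_spo2_csv <- function(path, ...) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "spo2") %in% names(d)))
    stop("expected columns time_s, spo2")
  if (nrow(d) < 2L) stop("empty signal")
  dt <- stats::median(diff(d$time_s))
  if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling rate")
  clean_signal(d$spo2, rate = 1 / dt, start_time = d$time_s[1], ...)
}

#' Read a hypnogram from CSV
#'
#' Expects columns `epoch` and `stage`.
#'
#' @param path CSV file path.
#' @param epoch_s epoch length in seconds.
#' @return a `hypnogram`.
#' @export
read_hypnogram_csv <- function(path, epoch_s = 30) {
  d <- utils::read.csv(path)
  if (!all(c("epoch", "stage") %in% names(d)))
    stop("expected columns epoch, stage")
  hypnogram(d$stage[order(d$epoch)], epoch_s = epoch_s)
}

#' Read respiratory events from CSV
#'
#' Expects columns `onset_s`, `duration_s`, `kind`.
#'
#' @param path CSV file path.
#' @return a respiratory event `data.frame` (see [respiratory_events()]).
#' @export
read_events_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("onset_s", "duration_s", "kind") %in% names(d)))
    stop("expected columns onset_s, duration_s, kind")
  respiratory_events(d$onset_s, d$duration_s, d$kind)
}
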