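#' Detect oxygen desaturation events
#'
#' An event is a fall of at least `threshold_pct` below the running local
#' baseline, where the baseline at each sample is the maximum valid SpO2
#' over the preceding `baseline_lookback_s`.  The event starts at the last
#' near-baseline sample before the fall, reaches its nadir, and ends when
#' the signal resaturates to within `resat_margin` of the event baseline
#' (or at an artifact boundary).  Events shorter than `min_event_s` or
#' longer than `max_event_s` are discarded; returned events are disjoint.
#'
#' @param signal a cleaned `oximetry_signal`.
#' @param threshold_pct desaturation depth threshold in %SpO2 (> 0).
#' @param baseline_lookback_s running-baseline window, seconds.
#' @param resat_margin resaturation margin in %SpO2.
#' @param min_event_s,max_event_s admissible event duration bounds, seconds.
#' @return a `data.frame` with columns `start_s`, `nadir_s`, `end_s`,
#'   `baseline`, `depth` (baseline minus nadir value).
#' @export
detect_desaturations <- function(signal, threshold_pct,
                                 baseline_lookback_s = 100,
                                 resat_margin = 1,
                                 min_event_s = 10, max_event_s = 600) {
  if (threshold_pct <= 0) stop("threshold_pct must be positive")
  if (!any(signal$valid)) stop("no valid samples")
  x <- signal$samples
  x[!signal$valid] <- NA_real_
  n <- length(x)
  rate <- signal$rate
  b <- running_baseline(x, rate, baseline_lookback_s)

  empty <- data.frame(start_s = numeric(0), nadir_s = numeric(0),
                      end_s = numeric(0), baseline = numeric(0),
                      depth = numeric(0))
  res <- empty
  i <- 1L
  while (i <= n) {
    if (is.na(x[i]) || is.na(b[i]) || b[i] - x[i] < threshold_pct) {
      i <- i + 1L
      next
    }
    base <- b[i]
    # walk back to the fall onset: last sample near baseline
    s <- i
    while (s > 1L && !is.na(x[s - 1L]) && x[s - 1L] < base - resat_margin)
      s <- s - 1L
    if (s > 1L && !is.na(x[s - 1L])) s <- s - 1L
    # walk forward to resaturation (or artifact / end of record)
    j <- i
    nadir <- i
    while (j < n && !is.na(x[j + 1L]) && x[j + 1L] < base - resat_margin) {
      j <- j + 1L
      if (x[j] < x[nadir]) nadir <- j
    }
    e <- if (j < n && !is.na(x[j + 1L])) j + 1L else j
    dur <- (e - s) / rate
    if (dur >= min_event_s && dur <= max_event_s && nadir > s) {
      t0 <- signal$start_time
      res <- rbind(res, data.frame(
        start_s = t0 + (s - 1L) / rate,
        nadir_s = t0 + (nadir - 1L) / rate,
        end_s   = t0 + (e - 1L) / rate,
        baseline = base,
        depth = base - x[nadir]))
    }
    i <- e + 1L
  }
  res
}

# Running local baseline: max of valid samples over the preceding
# lookback window (inclusive of the current sample).
running_baseline <- function(x, rate, lookback_s) {
  w <- max(1L, as.integer(round(lookback_s * rate)))
  xi <- ifelse(is.na(x), -Inf, x)
  n <- length(xi)
  if (n <= w) {
    b <- cummax(xi)
  } else {
    head_part <- cummax(xi[seq_len(w - 1L)])
    tail_part <- zoo::rollmax(xi, k = w, align = "right")
    b <- c(head_part, tail_part)
  }
  b[!is.finite(b)] <- NA_real_
  b
}

#' Oxygen desaturation index (ODI)
#'
#' Rate of desaturation events at a fixed depth threshold per hour of
#' sleep.  The denominator is the time in the selected stages.
#'
#' @param signal a cleaned `oximetry_signal` (already stage-restricted if
#'   a stage-specific ODI is wanted).
#' @param hyp a `hypnogram`.
#' @param threshold_pct desaturation threshold in %SpO2.
#' @param stages stage selector used for the TST denominator.
#' @param ... passed to [detect_desaturations()].
#' @return events per hour.
#' @export
odi <- function(signal, hyp, threshold_pct, stages = "sleep", ...) {
  tst <- tst_hours(hyp, stages)
  if (tst <= 0) stop("total sleep time is zero")
  ev <- detect_desaturations(signal, threshold_pct, ...)
  nrow(ev) / tst
}

#' Hypoxic burden
#'
#' Respiratory-event-anchored desaturation area per hour of sleep, using a
#' patient-specific search window derived from the ensemble-average SpO2
#' response around respiratory-event termination:
#' the window runs from the last pre-nadir maximum of the mean response to
#' its first post-nadir maximum.  For each event the pre-event baseline is
#' the maximum SpO2 in the `baseline_span_s` before event end, and the
#' area is the trapezoidal integral of `max(0, baseline - SpO2)` over the
#' window, in %·min.  The result is the summed area divided by total
#' sleep time.
#'
#' @param signal a cleaned `oximetry_signal`.
#' @param resp_events respiratory event table (see [respiratory_events()]).
#' @param hyp a `hypnogram`.
#' @param stages stage selector for the TST denominator.
#' @param ensemble_span_s half-width of the ensemble window around event
#'   end, seconds.
#' @param baseline_span_s pre-event baseline search span, seconds.
#' @return a list with `value` (%min/h), `window_pre_s`, `window_post_s`,
#'   and `per_event_areas` (%min).
#' @export
hypoxic_burden <- function(signal, resp_events, hyp, stages = "sleep",
                           ensemble_span_s = 240, baseline_span_s = 100) {
  tst <- tst_hours(hyp, stages)
  if (tst <= 0) stop("total sleep time is zero")
  if (is.null(resp_events) || nrow(resp_events) == 0L) {
    warning("no respiratory events; hypoxic burden is 0")
    return(list(value = 0, window_pre_s = NA_real_, window_post_s = NA_real_,
                per_event_areas = numeric(0)))
  }
  x <- signal$samples
  x[!signal$valid] <- NA_real_
  rate <- signal$rate
  n <- length(x)
  end_idx <- round((resp_events$onset + resp_events$duration -
                      signal$start_time) * rate) + 1L

  # ensemble-average response aligned on event end
  span <- as.integer(round(ensemble_span_s * rate))
  offs <- -span:span
  acc <- numeric(length(offs))
  cnt <- numeric(length(offs))
  for (e in end_idx) {
    idx <- e + offs
    ok <- idx >= 1L & idx <= n
    vals <- x[idx[ok]]
    fin <- !is.na(vals)
    acc[ok][fin] <- acc[ok][fin] + vals[fin]
    cnt[ok][fin] <- cnt[ok][fin] + 1
  }
  mean_resp <- ifelse(cnt > 0, acc / cnt, NA_real_)
  if (all(is.na(mean_resp))) stop("no valid samples around events")

  # the desaturation response lags event end; search the nadir there so a
  # neighbouring event's tail inside the ensemble span cannot capture it
  i_zero <- span + 1L
  i_nadir <- i_zero - 1L + which.min(mean_resp[i_zero:length(mean_resp)])
  pre <- mean_resp[seq_len(i_nadir)]
  i_pre <- max(which(pre == max(pre, na.rm = TRUE)))      # last pre-nadir max
  post <- mean_resp[i_nadir:length(mean_resp)]
  i_post <- i_nadir - 1L + min(which(post == max(post, na.rm = TRUE)))
  o1 <- offs[i_pre]; o2 <- offs[i_post]
  if (o2 <= o1) o2 <- o1 + 1L

  base_span <- as.integer(round(baseline_span_s * rate))
  areas <- vapply(end_idx, function(e) {
    bidx <- max(1L, e - base_span):min(n, e)
    base <- suppressWarnings(max(x[bidx], na.rm = TRUE))
    if (!is.finite(base)) return(NA_real_)
    widx <- max(1L, e + o1):min(n, e + o2)
    deficit <- pmax(0, base - x[widx])
    deficit[is.na(deficit)] <- 0            # artifacts contribute no area
    if (length(deficit) < 2L) return(0)
    sum((deficit[-1] + deficit[-length(deficit)]) / 2) / rate / 60
  }, numeric(1))
  areas <- areas[!is.na(areas)]
  list(value = sum(areas) / tst,
       window_pre_s = max(0, -o1 / rate),
       window_post_s = max(0, o2 / rate),
       per_event_areas = areas)
}
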