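#' Configuration for a synthetic oximetry night
#'
#' Defaults emulate a moderate-OSA night: 8 h at 1 Hz around a 96%
#' baseline, 15 desaturations/h of mean depth 4% with 20 s falls and 25 s
#' recoveries delayed 10 s after the respiratory event (circulatory lag),
#' 0.2% measurement noise, and a 20% REM fraction.
#'
#' @param duration_h night length, hours.
#' @param baseline baseline saturation, %SpO2.
#' @param event_rate respiratory events per hour.
#' @param depth_mean,depth_sd desaturation depth distribution, %SpO2.
#' @param desat_duration_s,resat_duration_s fall / recovery times, s.
#' @param noise_sd Gaussian measurement noise SD, %SpO2.
#' @param artifact_rate signal-loss dropouts per hour.
#' @param artifact_duration_s dropout length, s.
#' @param rem_fraction proportion of sleep spent in REM.
#' @param wake_fraction proportion of the record scored WAKE.
#' @param lag_s circulatory delay from respiratory-event end to
#'   desaturation onset, s.
#' @param resp_duration_s respiratory event length, s.
#' @param rate sampling rate, Hz.
#' @param epoch_s hypnogram epoch length, s.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return a named list of class `signal_config`.
#' @export
signal_config <- function(duration_h = 8, baseline = 96, event_rate = 15,
                          depth_mean = 4, depth_sd = 1,
                          desat_duration_s = 15, resat_duration_s = 20,
                          noise_sd = 0.2, artifact_rate = 0,
                          artifact_duration_s = 60, rem_fraction = 0.2,
                          wake_fraction = 0.05, lag_s = 10,
                          resp_duration_s = 20, rate = 1, epoch_s = 30,
                          seed = NULL) {
  cfg <- as.list(environment())
  stopifnot(cfg$duration_h > 0, cfg$event_rate >= 0, cfg$depth_mean >= 0,
            cfg$rem_fraction >= 0, cfg$rem_fraction <= 1,
            cfg$wake_fraction >= 0, cfg$wake_fraction < 1,
            cfg$rate > 0, cfg$noise_sd >= 0)
  class(cfg) <- "signal_config"
  cfg
}

#' Generate one synthetic oximetry night
#'
#' Respiratory events are placed by a homogeneous process at
#' `event_rate` without overlap (uniform placement conditional on
#' non-overlapping footprints).  Each event triggers a desaturation: a
#' linear fall of sampled depth starting `lag_s` after event end, then a
#' linear recovery, superimposed on the baseline with additive Gaussian
#' noise.  Optional signal-loss artifacts zero out stretches of samples.
#'
#' @param config a [signal_config()].
#' @return list with `signal` (cleaned `oximetry_signal`), `events`
#'   (respiratory event table), `hypnogram`, and `truth` (realized event
#'   count, depths, onsets, achieved events/h of sleep).
#' @export
generate_spo2 <- function(config) {
  stopifnot(inherits(config, "signal_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$rate
  n <- as.integer(round(config$duration_h * 3600 * fs))
  t_s <- (seq_len(n) - 1L) / fs

  # non-overlapping event placement
  foot <- config$resp_duration_s + config$lag_s +
    config$desat_duration_s + config$resat_duration_s + 5
  total_s <- config$duration_h * 3600
  if (config$event_rate * config$duration_h * foot > 0.9 * total_s)
    stop("infeasible packing: event footprints exceed the night length")
  k_max <- floor(0.9 * total_s / foot)
  k <- min(stats::rpois(1L, config$event_rate * config$duration_h), k_max)
  onsets <- if (k > 0) {
    sort(stats::runif(k, 0, total_s - k * foot)) + (seq_len(k) - 1L) * foot
  } else numeric(0)

  x <- rep(config$baseline, n)
  depths <- if (k > 0) {
    pmax(0.5, stats::rnorm(k, config$depth_mean, config$depth_sd))
  } else numeric(0)
  for (i in seq_len(k)) {
    fall0 <- onsets[i] + config$resp_duration_s + config$lag_s
    nadir_t <- fall0 + config$desat_duration_s
    end_t <- nadir_t + config$resat_duration_s
    seg <- t_s >= fall0 & t_s <= end_t
    tt <- t_s[seg]
    deficit <- ifelse(tt <= nadir_t,
                      depths[i] * (tt - fall0) / config$desat_duration_s,
                      depths[i] * (end_t - tt) / config$resat_duration_s)
    x[seg] <- x[seg] - deficit
  }
  if (config$noise_sd > 0) x <- x + stats::rnorm(n, 0, config$noise_sd)
  x <- pmin(x, 100)

  # signal-loss artifacts: device zeros
  n_art <- if (config$artifact_rate > 0)
    stats::rpois(1L, config$artifact_rate * config$duration_h) else 0L
  if (n_art > 0) {
    art_on <- stats::runif(n_art, 0, total_s - config$artifact_duration_s)
    for (a in art_on)
      x[t_s >= a & t_s < a + config$artifact_duration_s] <- 0
  }

  events <- respiratory_events(onsets, rep(config$resp_duration_s, k),
                               rep("hypopnea", max(k, 1L))[seq_len(k)])
  hyp <- synth_hypnogram(config$duration_h, config$epoch_s,
                         config$rem_fraction, config$wake_fraction)
  signal <- clean_signal(x, rate = fs, max_gap_s = 30)
  tst <- tst_hours(hyp)
  list(signal = signal, events = events, hypnogram = hyp,
       truth = list(event_count = k, depths = depths, onsets = onsets,
                    events_per_sleep_h = if (tst > 0) k / tst else NA_real_))
}

# Deterministic stage layout: leading wake, then sleep with REM periods
# spread over the later night (REM dominance late is the realistic shape).
synth_hypnogram <- function(duration_h, epoch_s, rem_fraction,
                            wake_fraction) {
  n_ep <- as.integer(round(duration_h * 3600 / epoch_s))
  stages <- rep("N2", n_ep)
  n_wake <- as.integer(round(wake_fraction * n_ep))
  if (n_wake > 0) stages[seq_len(n_wake)] <- "WAKE"
  sleep_idx <- which(stages != "WAKE")
  n_rem <- as.integer(round(rem_fraction * length(sleep_idx)))
  if (n_rem > 0) {
    n_per <- max(1L, n_rem %/% 4L)
    starts <- round(seq(0.3, 0.9, length.out = 4L) * length(sleep_idx))
    rem_idx <- unique(unlist(lapply(starts, function(s)
      seq(s, length.out = n_per))))
    rem_idx <- rem_idx[rem_idx <= length(sleep_idx)]
    rem_idx <- utils::head(rem_idx, n_rem)
    stages[sleep_idx[rem_idx]] <- "REM"
  }
  # a third of the remaining NREM split between N1 and N3 for realism
  nrem_idx <- which(stages == "N2")
  if (length(nrem_idx) > 6L) {
    stages[nrem_idx[seq(1L, length(nrem_idx), by = 7L)]] <- "N1"
    stages[nrem_idx[seq(4L, length(nrem_idx), by = 7L)]] <- "N3"
  }
  hypnogram(stages, epoch_s)
}

#' Configuration for a synthetic cohort
#'
#' Covariate distributions default to the demographics of a
#' community-based sleep cohort (mean age 63.5, BMI 28.8, 88% Caucasian,
#' 52% ever-smokers, 52% female).  Disease severity is drawn uniformly
#' over a mild-to-severe range; the survival outcome follows an
#' exponential (constant-baseline) proportional-hazards model whose
#' log-hazard is a linear function of z-scored oximetry features plus
#' covariate terms, with administrative censoring and a 2-year landmark.
#'
#' @param n number of participants.
#' @param age_mean,age_sd,bmi_mean,bmi_sd covariate distributions.
#' @param race_caucasian,smoking_ever,female category proportions.
#' @param feature_betas named numeric: log-hazard per SD of each named
#'   oximetry feature (names must be generatable features, see
#'   [generate_cohort()]).
#' @param covariate_betas named numeric log-hazards for `age` (per year),
#'   `bmi` (per unit), `race_other`, `smoking_ever`, `female`.
#' @param baseline_hazard events per person-year at covariate means.
#' @param censor_time_y administrative censoring time, years.
#' @param landmark_y landmark time, years (default 2).
#' @param event_rate_range,depth_range severity ranges (events/h, %SpO2).
#' @param missing_outcome_p proportion with missing CVD outcome.
#' @param central_shape1,central_shape2 Beta parameters of the
#'   central-apnea fraction.
#' @param seed integer seed or `NULL`.
#' @return a named list of class `cohort_config`.
#' @export
cohort_config <- function(n, age_mean = 63.5, age_sd = 10.5,
                          bmi_mean = 28.8, bmi_sd = 5.3,
                          race_caucasian = 0.883, smoking_ever = 0.52,
                          female = 0.518,
                          feature_betas = c(ODI4 = 0),
                          covariate_betas = c(age = 0.06, bmi = 0.01,
                                              race_other = 0,
                                              smoking_ever = 0.25,
                                              female = -0.3),
                          baseline_hazard = 0.016, censor_time_y = 12,
                          landmark_y = 2,
                          event_rate_range = c(2, 45),
                          depth_range = c(2, 8),
                          missing_outcome_p = 0,
                          central_shape1 = 2, central_shape2 = 18,
                          seed = NULL) {
  if (n <= 0) stop("n must be positive")
  if (baseline_hazard < 0) stop("baseline_hazard must be non-negative")
  if (censor_time_y <= landmark_y)
    stop("censor_time_y must exceed landmark_y")
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

# Features that the cohort generator can synthesize directly as smooth
# functions of latent severity (event rate, depth) plus noise.
.GENERATABLE <- c("AHI", "ODI2", "ODI3", "ODI4", "ODI5", "HypoxicBurden",
                  "T90", "SpO2Mean", "SpO2SD", "SampEn")

proxy_features <- function(rate, depth, cfg_signal = signal_config()) {
  n <- length(rate)
  span_min <- (cfg_signal$desat_duration_s + cfg_signal$resat_duration_s) /
    2 / 60
  odi_at <- function(th) rate * stats::pnorm(depth - th, sd = 1)
  data.frame(
    AHI = rate,
    ODI2 = odi_at(2), ODI3 = odi_at(3), ODI4 = odi_at(4), ODI5 = odi_at(5),
    HypoxicBurden = rate * depth * span_min *
      exp(stats::rnorm(n, 0, 0.1)),
    T90 = 100 * stats::plogis((rate * depth - 150) / 60) *
      exp(stats::rnorm(n, 0, 0.2)),
    SpO2Mean = 97 - 0.02 * rate * depth / 4 + stats::rnorm(n, 0, 0.5),
    SpO2SD = 0.5 + 0.15 * sqrt(rate) * depth / 4 + stats::rnorm(n, 0, 0.1),
    SampEn = pmin(1.5, 0.2 + 0.012 * rate + stats::rnorm(n, 0, 0.05)))
}

#' Generate a synthetic cohort
#'
#' Draws covariates and disease severity per participant, synthesizes
#' oximetry features, and simulates landmark survival outcomes.  In
#' `mode = "features"` the features are fast parametric proxies driven by
#' the latent severity (suitable for large statistical simulations); in
#' `mode = "signals"` each participant additionally gets a full synthetic
#' night via [generate_spo2()] for end-to-end pipeline runs.
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(sum(beta_f * z_f) + covariate terms)`; events
#' after `censor_time_y` are censored, and participants whose event falls
#' before `landmark_y` are flagged `prevalent` (mirroring exclusion of
#' disease within the first follow-up years).
#'
#' @param config a [cohort_config()].
#' @param mode `"features"` or `"signals"`.
#' @param signal_config a [signal_config()] template for
#'   `mode = "signals"`; per-participant event rate and depth override
#'   its `event_rate` / `depth_mean`.
#' @return list with `participants` (covariates, severity, outcomes and
#'   proxy features) and, in signals mode, `nights` (list of
#'   [generate_spo2()] results, one per participant).
#' @export
generate_cohort <- function(config, mode = c("features", "signals"),
                            signal_config = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  mode <- match.arg(mode)
  unknown <- setdiff(names(config$feature_betas), .GENERATABLE)
  if (length(unknown))
    stop("unknown feature name(s) in feature_betas: ",
         paste(unknown, collapse = ", "))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n

  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  bmi <- stats::rnorm(n, config$bmi_mean, config$bmi_sd)
  race <- ifelse(stats::runif(n) < config$race_caucasian,
                 "Caucasian", "other")
  smoking <- ifelse(stats::runif(n) < config$smoking_ever, "ever", "never")
  sex <- ifelse(stats::runif(n) < config$female, "female", "male")
  central <- stats::rbeta(n, config$central_shape1, config$central_shape2)

  rate_ev <- stats::runif(n, config$event_rate_range[1],
                          config$event_rate_range[2])
  depth <- stats::runif(n, config$depth_range[1], config$depth_range[2])
  sim_signal_cfg <- if (is.null(signal_config)) signal_config_default()
                    else signal_config
  feats <- proxy_features(rate_ev, depth, sim_signal_cfg)

  cb <- config$covariate_betas
  lp <- cb[["age"]] * (age - config$age_mean) +
    cb[["bmi"]] * (bmi - config$bmi_mean) +
    cb[["race_other"]] * (race == "other") +
    cb[["smoking_ever"]] * (smoking == "ever") +
    cb[["female"]] * (sex == "female")
  for (f in names(config$feature_betas)) {
    z <- (feats[[f]] - mean(feats[[f]])) / stats::sd(feats[[f]])
    lp <- lp + config$feature_betas[[f]] * z
  }
  haz <- config$baseline_hazard * exp(lp)
  t_event <- if (config$baseline_hazard > 0) stats::rexp(n, haz) else
    rep(Inf, n)
  cvd_event <- t_event <= config$censor_time_y
  followup <- pmin(t_event, config$censor_time_y)
  cvd_time <- ifelse(cvd_event, t_event, NA_real_)
  prevalent <- cvd_event & t_event < config$landmark_y
  if (config$missing_outcome_p > 0) {
    drop <- stats::runif(n) < config$missing_outcome_p
    cvd_event[drop] <- NA
    cvd_time[drop] <- NA_real_
  }

  participants <- data.frame(
    id = sprintf("synth-%04d", seq_len(n)),
    age = age, bmi = bmi, race = race, smoking = smoking, sex = sex,
    central_apnea_fraction = central,
    event_rate = rate_ev, depth = depth,
    feats,
    followup_y = followup, cvd_event = cvd_event, cvd_time_y = cvd_time,
    prevalent = prevalent,
    stringsAsFactors = FALSE, check.names = FALSE)

  out <- list(participants = participants, config = config)
  if (mode == "signals") {
    base_cfg <- if (is.null(signal_config)) signal_config_default()
                else signal_config
    seeds <- if (!is.null(config$seed))
      config$seed + seq_len(n) else rep(list(NULL), n)
    out$nights <- lapply(seq_len(n), function(i) {
      cfg_i <- base_cfg
      cfg_i$event_rate <- rate_ev[i]
      cfg_i$depth_mean <- depth[i]
      cfg_i$seed <- if (is.list(seeds)) NULL else
        as.integer(seeds[i] %% .Machine$integer.max)
      generate_spo2(cfg_i)
    })
    # AHI in the participant table becomes the realized per-sleep-hour rate
    out$participants$AHI <- vapply(out$nights, function(nt)
      nt$truth$events_per_sleep_h, numeric(1))
  }
  out
}

signal_config_default <- function() signal_config()
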