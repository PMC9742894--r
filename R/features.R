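#' Feature extraction configuration
#'
#' Collects every tunable of the four feature families in one place.
#' Defaults follow conventional nocturnal-oximetry practice; each is a
#' plain value so a configuration can round-trip through JSON.
#'
#' @param floor_pct physiologic validity floor, %SpO2.
#' @param max_gap_s longest artifact gap bridged by interpolation, s.
#' @param odi_thresholds desaturation depth thresholds, %SpO2.
#' @param baseline_lookback_s running-baseline window for event
#'   detection, s.
#' @param resat_margin resaturation margin, %SpO2.
#' @param min_event_s,max_event_s admissible desaturation durations, s.
#' @param hb_ensemble_span_s,hb_baseline_span_s hypoxic-burden ensemble
#'   half-span and pre-event baseline span, s.
#' @param tx_thresholds TX thresholds, %SpO2.
#' @param tx_inclusive TX uses `<=` when `TRUE`.
#' @param psd_segment_s,psd_overlap Welch segment length (s) and overlap.
#' @param psd_min_duration_s minimum signal length for the PSD, s.
#' @param full_band,osa_band analysis bands in Hz.  The OSA band default
#'   0.00417--0.05 Hz spans periodic desaturations at 15--180 events/h.
#' @param entropy_log_base base of the spectral-entropy logarithm.
#' @param resample_rate_hz rate for the non-linear family, Hz.
#' @param sampen_m,sampen_r,sampen_r_mode sample-entropy parameters.
#' @param ctm_rho CTM radius, %SpO2.
#' @return a named list of class `oximetry_config`.
#' @export
oximetry_config <- function(floor_pct = 50, max_gap_s = 30,
                            odi_thresholds = c(2, 3, 4, 5),
                            baseline_lookback_s = 100, resat_margin = 1,
                            min_event_s = 10, max_event_s = 600,
                            hb_ensemble_span_s = 240,
                            hb_baseline_span_s = 100,
                            tx_thresholds = seq(80, 94, by = 2),
                            tx_inclusive = TRUE,
                            psd_segment_s = 2048, psd_overlap = 0.5,
                            psd_min_duration_s = 3600,
                            full_band = c(0, 0.1),
                            osa_band = c(0.00417, 0.05),
                            entropy_log_base = exp(1),
                            resample_rate_hz = 0.2,
                            sampen_m = 1, sampen_r = 0.25,
                            sampen_r_mode = "sd",
                            ctm_rho = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "oximetry_config"
  cfg
}

#' Oximetry feature names by analysis family
#'
#' @return named list of character vectors with families
#'   `desaturation` (5), `time_series` (14), `psd` (10), `nonlinear` (2).
#' @export
feature_families <- function() {
  list(
    desaturation = c("ODI2", "ODI3", "ODI4", "ODI5", "HypoxicBurden"),
    time_series = c("SpO2Mean", "SpO2SD", "SpO2Skew", "SpO2Kurt",
                    "SpO2Median", "SpO2Nadir",
                    paste0("T", seq(80, 94, by = 2))),
    psd = c("FFB_Mean", "FFB_SD", "FFB_Skew", "FFB_Kurt", "FFB_SpecEnt",
            "OSAFB_Mean", "OSAFB_SD", "OSAFB_Skew", "OSAFB_Kurt",
            "OSAFB_SpecEnt"),
    nonlinear = c("SampEn", "CTM"))
}

#' Family of a feature name
#' @param feature character vector of feature names.
#' @return character vector of family labels (`NA` for unknown names,
#'   `"comparison"` for `AHI`).
#' @export
feature_family_of <- function(feature) {
  fam <- feature_families()
  lut <- c(stats::setNames(rep(names(fam), lengths(fam)), unlist(fam)),
           AHI = "comparison")
  unname(lut[feature])
}

#' Extract the full oximetry feature vector
#'
#' Computes all 31 oximetry patterns (plus AHI from the respiratory event
#' annotations) for one night, for the requested sleep stratum.  A family
#' whose preconditions fail (e.g. a too-short stratum for the PSD) yields
#' `NA` features and a recorded reason, never a silent zero.
#'
#' @param signal a cleaned `oximetry_signal`.
#' @param hyp a `hypnogram`.
#' @param resp_events respiratory event table (may have zero rows).
#' @param config an [oximetry_config()].
#' @param stratum `"total"`, `"NREM"` or `"REM"`.
#' @return a one-row `data.frame` with columns `stratum`, the 31 features,
#'   and `AHI`; attribute `missing_reasons` names any failed computations.
#' @export
extract_all <- function(signal, hyp, resp_events = NULL,
                        config = oximetry_config(),
                        stratum = c("total", "NREM", "REM")) {
  stratum <- match.arg(stratum)
  stages <- switch(stratum, total = "sleep", NREM = "NREM", REM = "REM")
  fam <- feature_families()
  vals <- stats::setNames(
    rep(NA_real_, length(unlist(fam))), unlist(fam))
  reasons <- character(0)
  note <- function(what, e) {
    reasons[[what]] <<- conditionMessage(e)
  }

  sig <- tryCatch(restrict_to_stage(signal, hyp, stages),
                  error = function(e) { note("stratum", e); NULL })
  tst <- tst_hours(hyp, stages)

  if (!is.null(sig) && any(sig$valid) && tst > 0) {
    # desaturation characteristics
    for (th in config$odi_thresholds) {
      nm <- paste0("ODI", th)
      vals[nm] <- tryCatch(
        odi(sig, hyp, th, stages = stages,
            baseline_lookback_s = config$baseline_lookback_s,
            resat_margin = config$resat_margin,
            min_event_s = config$min_event_s,
            max_event_s = config$max_event_s),
        error = function(e) { note(nm, e); NA_real_ })
    }
    vals["HypoxicBurden"] <- tryCatch(
      suppressWarnings(
        hypoxic_burden(sig, resp_events, hyp, stages = stages,
                       ensemble_span_s = config$hb_ensemble_span_s,
                       baseline_span_s = config$hb_baseline_span_s)$value),
      error = function(e) { note("HypoxicBurden", e); NA_real_ })

    # time-series distribution
    mom <- tryCatch(distribution_moments(sig),
                    error = function(e) { note("moments", e); NULL })
    if (!is.null(mom)) {
      vals["SpO2Mean"] <- mom[["mean"]]
      vals["SpO2SD"] <- mom[["sd"]]
      vals["SpO2Skew"] <- mom[["skewness"]]
      vals["SpO2Kurt"] <- mom[["kurtosis"]]
    }
    cm <- tryCatch(cumulative_metrics(sig),
                   error = function(e) { note("cumulative", e); NULL })
    if (!is.null(cm)) {
      vals["SpO2Median"] <- cm[["median"]]
      vals["SpO2Nadir"] <- cm[["nadir"]]
    }
    tx <- tryCatch(time_below(sig, config$tx_thresholds,
                              config$tx_inclusive),
                   error = function(e) { note("tx", e); NULL })
    if (!is.null(tx)) vals[names(tx)] <- tx

    # power spectral density
    psd <- tryCatch(estimate_psd(sig, segment_s = config$psd_segment_s,
                                 overlap = config$psd_overlap,
                                 min_duration_s = config$psd_min_duration_s),
                    error = function(e) { note("psd", e); NULL })
    if (!is.null(psd)) {
      bf <- function(band, prefix) {
        v <- tryCatch(band_features(psd, band, config$entropy_log_base),
                      error = function(e) { note(prefix, e); NULL })
        if (!is.null(v)) {
          vals[paste0(prefix, c("_Mean", "_SD", "_Skew", "_Kurt",
                                "_SpecEnt"))] <<-
            v[c("mean", "sd", "skewness", "kurtosis", "spectral_entropy")]
        }
      }
      bf(config$full_band, "FFB")
      bf(config$osa_band, "OSAFB")
    }

    # non-linear
    low <- tryCatch(resample_signal(sig, config$resample_rate_hz),
                    error = function(e) { note("resample", e); NULL })
    if (!is.null(low)) {
      vals["SampEn"] <- tryCatch(
        suppressWarnings(
          sample_entropy(low, m = config$sampen_m, r = config$sampen_r,
                         r_mode = config$sampen_r_mode)),
        error = function(e) { note("SampEn", e); NA_real_ })
      vals["CTM"] <- tryCatch(
        central_tendency_measure(low, rho = config$ctm_rho),
        error = function(e) { note("CTM", e); NA_real_ })
    }
  } else {
    reasons[["all"]] <- "no valid samples in stratum"
  }

  ahi <- if (!is.null(resp_events) && tst > 0) nrow(resp_events) / tst
         else NA_real_
  out <- data.frame(stratum = stratum, t(vals), AHI = ahi,
                    stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "missing_reasons") <- reasons
  out
}

#' Z-standardize a feature matrix across participants
#'
#' Centers and scales each feature column to mean 0, SD 1 using the
#' non-missing values; missing entries remain missing.  The returned
#' scaling record preserves the per-SD interpretation of downstream
#' hazard ratios.
#'
#' @param mat numeric matrix or data frame, participants in rows, features
#'   in columns.
#' @return list with `z` (matrix), `center`, `scale`.
#' @export
zscore_matrix <- function(mat) {
  m <- as.matrix(mat)
  if (!is.numeric(m)) stop("feature matrix must be numeric")
  center <- apply(m, 2L, mean, na.rm = TRUE)
  scale_ <- apply(m, 2L, stats::sd, na.rm = TRUE)
  n_ok <- apply(m, 2L, function(col) sum(!is.na(col)))
  if (any(n_ok < 2L))
    stop("fewer than 2 non-missing values for feature(s): ",
         paste(colnames(m)[n_ok < 2L], collapse = ", "))
  zero <- !is.na(scale_) & scale_ == 0
  if (any(zero))
    stop("zero-variance feature(s): ",
         paste(colnames(m)[zero], collapse = ", "))
  z <- sweep(sweep(m, 2L, center, "-"), 2L, scale_, "/")
  list(z = z, center = center, scale = scale_)
}

#' Write / read a feature matrix with its configuration sidecar
#'
#' The CSV holds one row per participant-stratum with full double
#' precision; the JSON sidecar records the extraction configuration so a
#' run can be reproduced.
#'
#' @param features data frame of features (with `id` and `stratum`).
#' @param path CSV output path.
#' @param config the [oximetry_config()] used (optional).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path, config = NULL) {
  df <- features
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) sprintf("%.17g", col))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config),
                         paste0(tools::file_path_sans_ext(path), ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  for (nm in names(d)) {
    if (nm %in% c("id", "stratum")) next
    d[[nm]] <- as.numeric(d[[nm]])
  }
  d
}
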