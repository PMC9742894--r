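#' Pipeline configuration
#'
#' One object describing an end-to-end run: where the input comes from
#' (simulated cohort or CSV files on disk), the feature-extraction
#' configuration, the association settings, and the output directory.
#'
#' @param mode `"simulate"` or `"csv"`.
#' @param out_dir output directory (created if absent).
#' @param cohort a [cohort_config()] (simulate mode).
#' @param signal a [signal_config()] template (simulate mode).
#' @param features an [oximetry_config()].
#' @param participants_csv,signal_dir CSV-mode inputs: a participant
#'   table (columns as in [apply_inclusion()] plus `id`, `age`, `bmi`,
#'   `race`, `smoking`, `sex`) and a directory with per-participant
#'   `<id>_spo2.csv`, `<id>_hypnogram.csv`, `<id>_events.csv`.
#' @param strata sleep strata to extract (`"total"`, `"NREM"`, `"REM"`).
#' @param landmark_y,min_ahi,central_max inclusion-filter settings.
#' @param fdr_q FDR level.
#' @param seed integer seed for simulate mode.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "csv"), out_dir = NULL,
                            cohort = NULL, signal = NULL,
                            features = oximetry_config(),
                            participants_csv = NULL, signal_dir = NULL,
                            strata = "total",
                            landmark_y = 2, min_ahi = 5,
                            central_max = 0.5, fdr_q = 0.05,
                            seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "simulate" && is.null(cohort))
    stop("simulate mode needs a cohort_config")
  if (mode == "csv" && (is.null(participants_csv) || is.null(signal_dir)))
    stop("csv mode needs participants_csv and signal_dir")
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the oximetry phenotyping pipeline
#'
#' simulate/load -> clean -> extract 31 features per participant and
#' stratum -> inclusion filter -> association protocol.  Per-participant
#' failures are logged and skipped; the run errors only if no participant
#' succeeds.  Deterministic given the seed in simulate mode.
#'
#' @param config a [pipeline_config()].
#' @return list with `features` (per-participant feature rows),
#'   `cohort` (post-filter), `tally`, `associations`, and `log`
#'   (per-participant status), written to `out_dir` when set
#'   (`features.csv`, `associations.csv`, `participants.csv`, `log.csv`,
#'   `config.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$mode == "simulate") {
    ccfg <- config$cohort
    ccfg$seed <- config$seed
    sim <- generate_cohort(ccfg, mode = "signals",
                           signal_config = config$signal)
    participants <- sim$participants
    nights <- sim$nights
    ids <- participants$id
  } else {
    participants <- utils::read.csv(config$participants_csv,
                                    stringsAsFactors = FALSE)
    ids <- participants$id
    nights <- NULL
  }

  feat_rows <- list()
  log_rows <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    res <- tryCatch({
      if (config$mode == "simulate") {
        nt <- nights[[i]]
        sig <- nt$signal; hyp <- nt$hypnogram; ev <- nt$events
      } else {
        p <- function(suffix)
          file.path(config$signal_dir, paste0(id, suffix))
        sig <- read_spo2_csv(p("_spo2.csv"),
                             max_gap_s = config$features$max_gap_s,
                             floor_pct = config$features$floor_pct)
        hyp <- read_hypnogram_csv(p("_hypnogram.csv"))
        ev <- if (file.exists(p("_events.csv")))
          read_events_csv(p("_events.csv")) else NULL
      }
      one <- lapply(config$strata, function(st)
        extract_all(sig, hyp, ev, config$features, stratum = st))
      fv <- do.call(rbind, one)
      fv <- cbind(id = id, fv, stringsAsFactors = FALSE)
      list(ok = TRUE, fv = fv,
           n_missing = sum(is.na(as.matrix(
             fv[, unlist(feature_families()), drop = FALSE]))))
    }, error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
    if (res$ok) {
      feat_rows[[length(feat_rows) + 1L]] <- res$fv
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        id = id, status = "ok", detail = sprintf("%d missing features",
                                                 res$n_missing))
    } else {
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        id = id, status = "skipped", detail = res$msg)
    }
  }
  if (!length(feat_rows)) stop("no participants could be analyzed")
  features <- do.call(rbind, feat_rows)
  run_log <- do.call(rbind, log_rows)

  # association on the total-sleep stratum
  tot <- features[features$stratum == "total", , drop = FALSE]
  keep_cols <- setdiff(names(tot), c("stratum"))
  merged <- merge(participants[, setdiff(names(participants),
                                         c(unlist(feature_families()),
                                           "AHI")),
                               drop = FALSE],
                  tot[, keep_cols, drop = FALSE], by = "id")
  incl <- apply_inclusion(merged, landmark_y = config$landmark_y,
                          min_ahi = config$min_ahi,
                          central_max = config$central_max)
  if (incl$n_included == 0L) stop("no eligible participants")
  assoc <- associate_features(incl$cohort, fdr_q = config$fdr_q)

  bundle <- list(features = features, cohort = incl$cohort,
                 tally = incl$tally, associations = assoc, log = run_log,
                 config = config)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) write_feature_matrix(
    df, file.path(out_dir, name))
  w(bundle$features, "features.csv")
  w(bundle$associations, "associations.csv")
  w(bundle$cohort, "participants.csv")
  utils::write.csv(bundle$log, file.path(out_dir, "log.csv"),
                   row.names = FALSE)
  cfg <- bundle$config
  cfg$features <- unclass(cfg$features)
  cfg$cohort <- unclass(cfg$cohort)
  cfg$signal <- if (!is.null(cfg$signal)) unclass(cfg$signal)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(out_dir)
}

#' Forest-style association table
#'
#' Orders results for presentation: the AHI comparison row(s) first, then
#' families in the order desaturation, time series, PSD, non-linear, with
#' features in their declared order, stably within each stratum.
#'
#' @param results output of [associate_features()].
#' @return reordered `data.frame` with a `label` column
#'   (`"HR (95% CI)"` text).
#' @export
render_forest_table <- function(results) {
  if (is.null(results) || nrow(results) == 0L) stop("no results to render")
  fam_order <- c("comparison", "desaturation", "time_series", "psd",
                 "nonlinear")
  feat_order <- c("AHI", unlist(feature_families(), use.names = FALSE))
  res <- results
  res$.fam <- match(res$family, fam_order)
  res$.feat <- match(res$feature, feat_order)
  res$.str <- match(res$stratum, c("all", "men", "women"))
  res <- res[order(res$.str, res$.fam, res$.feat), , drop = FALSE]
  res$label <- ifelse(
    is.na(res$hr), "not estimable",
    sprintf("%.2f (%.2f-%.2f)", res$hr, res$ci_lo, res$ci_hi))
  res[, setdiff(names(res), c(".fam", ".feat", ".str")), drop = FALSE]
}
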