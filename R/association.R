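#' Apply cohort inclusion criteria
#'
#' Keeps participants with OSA (`ahi >= min_ahi`), predominantly
#' obstructive events (`central_apnea_fraction < central_max`), a
#' non-missing outcome, and no disease event before the landmark.  The
#' follow-up clock is re-anchored at the landmark so downstream survival
#' models count time and events from the landmark onward.
#'
#' @param participants data frame with columns `ahi` (or `AHI`),
#'   `central_apnea_fraction`, `followup_y`, `cvd_event`, `cvd_time_y`.
#' @param landmark_y landmark time, years (default 2).
#' @param min_ahi OSA threshold, events/h (default 5).
#' @param central_max exclusion threshold on the central-apnea fraction.
#' @return list with `cohort` (filtered, plus `time_y` re-anchored at the
#'   landmark) and `tally` (named exclusion counts).
#' @export
apply_inclusion <- function(participants, landmark_y = 2, min_ahi = 5,
                            central_max = 0.5) {
  d <- participants
  if (!"ahi" %in% names(d) && "AHI" %in% names(d)) d$ahi <- d$AHI
  need <- c("ahi", "central_apnea_fraction", "followup_y", "cvd_event",
            "cvd_time_y")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))

  reason <- rep(NA_character_, nrow(d))
  reason[is.na(reason) & is.na(d$cvd_event)] <- "missing outcome"
  reason[is.na(reason) & d$ahi < min_ahi] <- "no OSA"
  reason[is.na(reason) &
           d$central_apnea_fraction >= central_max] <- "central apnea"
  reason[is.na(reason) & !is.na(d$cvd_event) & d$cvd_event &
           d$cvd_time_y < landmark_y] <- "CVD before landmark"

  keep <- is.na(reason)
  tally <- table(factor(reason[!keep],
                        levels = c("missing outcome", "no OSA",
                                   "central apnea", "CVD before landmark")))
  cohort <- d[keep, , drop = FALSE]
  cohort$time_y <- pmax(cohort$followup_y - landmark_y, 0)
  list(cohort = cohort, tally = c(tally), n_included = sum(keep))
}

#' Independent two-sample t-test for a feature by outcome group
#'
#' @param x numeric feature column.
#' @param group logical or two-level indicator (e.g. incident disease).
#' @param pooled use the pooled-variance (equal-variance) statistic
#'   (default); `FALSE` gives the Welch form.
#' @return list with `t`, `p`, `df`.
#' @export
group_ttest <- function(x, group, pooled = TRUE) {
  g <- as.logical(group)
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- g[ok]
  if (sum(g) < 2L || sum(!g) < 2L) stop("fewer than 2 per group")
  if (stats::sd(x[g]) == 0 && stats::sd(x[!g]) == 0)
    return(list(t = NA_real_, p = NA_real_, df = NA_real_))
  tt <- stats::t.test(x[g], x[!g], var.equal = pooled)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Spearman rank correlation of a feature with AHI
#'
#' Midrank tie handling; the p value uses the t approximation.
#'
#' @param x numeric feature column.
#' @param ahi numeric AHI column.
#' @return list with `rho`, `p`.
#' @export
spearman_ahi <- function(x, ahi) {
  ok <- !is.na(x) & !is.na(ahi)
  if (sum(ok) < 3L) stop("fewer than 3 complete pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(ahi[ok]) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  ct <- suppressWarnings(
    stats::cor.test(x[ok], ahi[ok], method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Cox proportional-hazards model for one standardized feature
#'
#' Fits `Surv(time, event) ~ z + age + race + smoking + bmi (+ sex)` by
#' partial likelihood (Efron ties by default) and reports the hazard
#' ratio per 1 SD of the feature with its Wald 95% CI.  The sex
#' covariate is dropped in sex-stratified models.
#'
#' @param data data frame with `time_y`, `cvd_event`, `age`, `bmi`,
#'   `race`, `smoking`, `sex` and the z-scored feature column `z`.
#' @param feature feature name (for labeling).
#' @param stratum `"all"`, `"men"` or `"women"`; subsets and drops the
#'   sex term when stratified.
#' @param ties tie handling, `"efron"` (default) or `"breslow"`.
#' @return one-row `data.frame`: `feature`, `stratum`, `n`, `events`,
#'   `hr`, `ci_lo`, `ci_hi`, `p`, `converged`.
#' @export
fit_cox <- function(data, feature = "feature",
                    stratum = c("all", "men", "women"),
                    ties = c("efron", "breslow")) {
  stratum <- match.arg(stratum)
  ties <- match.arg(ties)
  d <- switch(stratum,
              all = data,
              men = data[data$sex == "male", , drop = FALSE],
              women = data[data$sex == "female", , drop = FALSE])
  covs <- c("age", "race", "smoking", "bmi",
            if (stratum == "all") "sex")
  keep <- stats::complete.cases(
    d[, c("time_y", "cvd_event", "z", covs), drop = FALSE])
  d <- d[keep, , drop = FALSE]
  d <- d[d$time_y > 0, , drop = FALSE]
  flag <- function() data.frame(
    feature = feature, stratum = stratum, n = nrow(d),
    events = sum(d$cvd_event), hr = NA_real_, ci_lo = NA_real_,
    ci_hi = NA_real_, p = NA_real_, converged = FALSE,
    stringsAsFactors = FALSE)
  if (nrow(d) < 10L || sum(d$cvd_event) < 2L) return(flag())
  fml <- stats::as.formula(paste(
    "survival::Surv(time_y, cvd_event) ~ z +",
    paste(covs, collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(survival::coxph(fml, data = d, ties = ties)),
    error = function(e) NULL)
  if (is.null(fit)) return(flag())
  s <- summary(fit)
  beta <- stats::coef(fit)[["z"]]
  se <- s$coefficients["z", "se(coef)"]
  if (!is.finite(beta) || !is.finite(se) || se > 100) return(flag())
  data.frame(
    feature = feature, stratum = stratum, n = nrow(d),
    events = sum(d$cvd_event),
    hr = exp(beta), ci_lo = exp(beta - 1.959964 * se),
    ci_hi = exp(beta + 1.959964 * se),
    p = s$coefficients["z", "Pr(>|z|)"], converged = TRUE,
    stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up adjustment within one family: for ordered p values,
#' `p_bh[(i)] = min over j >= i of m * p[(j)] / j`, capped at 1.
#'
#' @param p numeric vector of p values in `[0, 1]` (NAs pass through).
#' @return adjusted p values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must be in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  o <- order(p[ok])
  adj <- pmin(1, rev(cummin(rev(m * p[ok][o] / seq_len(m)))))
  out[ok[o]] <- adj
  out
}

#' Run the full association protocol over a feature matrix
#'
#' For each oximetry feature (plus AHI as a comparison predictor fitted
#' through the identical model path) and each stratum (`all`, `men`,
#' `women`): z-standardize over the stratum's complete cases, fit the
#' adjusted Cox model, then control the FDR with Benjamini-Hochberg
#' within each analysis family and stratum (AHI is excluded from the
#' families).  Also reports the per-feature t-test between outcome
#' groups and Spearman correlation with AHI in the full cohort.
#'
#' @param cohort filtered cohort from [apply_inclusion()] joined with the
#'   feature columns (one row per participant).
#' @param features character vector of feature columns to model; default
#'   all 31 patterns present plus AHI.
#' @param strata which strata to fit.
#' @param fdr_q FDR level (default 0.05).
#' @param ties Cox tie handling.
#' @return `data.frame` with one row per feature-stratum: family, n,
#'   events, hr, ci_lo, ci_hi, p, p_bh, significant, plus `t_p` and
#'   `spearman_ahi` (all-stratum screens).
#' @export
associate_features <- function(cohort,
                               features = NULL,
                               strata = c("all", "men", "women"),
                               fdr_q = 0.05,
                               ties = "efron") {
  all_feats <- unlist(feature_families(), use.names = FALSE)
  if (is.null(features))
    features <- c("AHI", intersect(all_feats, names(cohort)))
  missing_cols <- setdiff(features, names(cohort))
  if (length(missing_cols))
    stop("feature column(s) not found: ",
         paste(missing_cols, collapse = ", "))

  rows <- list()
  for (st in strata) {
    for (f in features) {
      d <- cohort
      x <- d[[f]]
      ok <- !is.na(x)
      if (sum(ok) >= 2L && stats::sd(x[ok]) > 0) {
        d$z <- (x - mean(x[ok])) / stats::sd(x[ok])
      } else {
        d$z <- NA_real_
      }
      rows[[length(rows) + 1L]] <- fit_cox(d, feature = f, stratum = st,
                                           ties = ties)
    }
  }
  res <- do.call(rbind, rows)
  res$family <- feature_family_of(res$feature)

  # FDR within analysis family, per stratum; AHI excluded ("comparison")
  res$p_bh <- NA_real_
  for (st in unique(res$stratum)) {
    for (fam in setdiff(unique(res$family), "comparison")) {
      sel <- res$stratum == st & res$family == fam
      res$p_bh[sel] <- bh_adjust(res$p[sel])
    }
  }
  res$significant <- !is.na(res$p_bh) & res$p_bh <= fdr_q

  # univariate screens in the full cohort
  res$t_p <- NA_real_
  res$spearman_ahi <- NA_real_
  for (f in unique(res$feature)) {
    sel <- res$feature == f & res$stratum == "all"
    if (!any(sel)) next
    tp <- tryCatch(group_ttest(cohort[[f]], cohort$cvd_event)$p,
                   error = function(e) NA_real_)
    rho <- if (f == "AHI") 1 else
      tryCatch(spearman_ahi(cohort[[f]], cohort$AHI)$rho,
               error = function(e) NA_real_)
    res$t_p[sel] <- tp
    res$spearman_ahi[sel] <- rho
  }
  rownames(res) <- NULL
  res
}
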