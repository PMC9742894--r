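make_participants <- function() {
  data.frame(
    id = paste0("p", 1:6),
    ahi = c(4.9, 20, 20, 20, 20, 20),
    central_apnea_fraction = c(0.1, 0.6, 0.1, 0.1, 0.1, 0.1),
    followup_y = c(10, 10, 1.5, 10, 10, 10),
    cvd_event = c(FALSE, FALSE, TRUE, NA, TRUE, FALSE),
    cvd_time_y = c(NA, NA, 1.5, NA, 6, NA))
}

test_that("inclusion filter applies each exclusion rule with a tally", {
  res <- apply_inclusion(make_participants())
  expect_equal(res$n_included, 2L)
  expect_equal(sort(res$cohort$id), c("p5", "p6"))
  expect_equal(unname(res$tally[c("no OSA", "central apnea",
                                  "CVD before landmark",
                                  "missing outcome")]),
               c(1L, 1L, 1L, 1L))
})

test_that("the follow-up clock is re-anchored at the landmark", {
  res <- apply_inclusion(make_participants(), landmark_y = 2)
  expect_equal(res$cohort$time_y, res$cohort$followup_y - 2)
  # nobody included can contribute an event before the landmark
  ev <- res$cohort$cvd_event & !is.na(res$cohort$cvd_event)
  expect_true(all(res$cohort$cvd_time_y[ev] >= 2))
})

test_that("pooled t-test matches the closed form and its symmetries", {
  r <- group_ttest(c(1, 2, 3, 4, 5, 6), c(rep(TRUE, 3), rep(FALSE, 3)))
  expect_equal(r$t, -3.67423461417477, tolerance = 1e-10)

  x <- c(rnorm(10, 0), rnorm(10, 1))
  g <- rep(c(TRUE, FALSE), each = 10)
  a <- group_ttest(x, g)
  b <- group_ttest(x, !g)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)

  same <- group_ttest(rep(c(1, 2, 3), 2), rep(c(TRUE, FALSE), each = 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("Spearman correlation hits its exact extremes and null", {
  ahi <- c(5, 12, 30, 45, 8, 22)
  expect_equal(spearman_ahi(ahi, ahi)$rho, 1)
  expect_equal(spearman_ahi(-ahi, ahi)$rho, -1)
  set.seed(83)
  rho <- spearman_ahi(rnorm(1000), rnorm(1000))$rho
  expect_lt(abs(rho), 0.07)
})

test_that("BH adjustment matches the hand-checked step-up rule", {
  adj <- bh_adjust(c(0.01, 0.02, 0.03, 0.04))
  expect_true(all(adj <= 0.05))
  expect_equal(adj, c(0.04, 0.04, 0.04, 0.04))

  expect_equal(bh_adjust(rep(0.9, 5)), rep(0.9, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(89)
  for (i in 1:50) {
    p <- runif(sample(2:20, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p))
    expect_equal(adj <= 0.05, brute_bh_flags(p, 0.05))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("the Cox wrapper maximizes the partial likelihood (oracle check)", {
  set.seed(97)
  n <- 40
  d <- data.frame(
    time_y = rexp(n, 0.2), cvd_event = runif(n) < 0.6,
    age = rnorm(n, 60, 8), bmi = rnorm(n, 28, 4),
    race = sample(c("Caucasian", "other"), n, TRUE),
    smoking = sample(c("never", "ever"), n, TRUE),
    sex = sample(c("male", "female"), n, TRUE), z = rnorm(n))
  fit <- fit_cox(d, "toy", "all")
  X <- cbind(d$z, d$age, d$race == "other", d$smoking == "never",
             d$bmi, d$sex == "male")
  beta <- brute_cox_beta(d$time_y, d$cvd_event, X)
  expect_equal(fit$hr, exp(beta[1]), tolerance = 1e-4)
  expect_true(fit$converged)
  expect_true(fit$ci_lo <= fit$hr && fit$hr <= fit$ci_hi)
})

test_that("Cox per-SD hazard ratios are invariant to units of time and feature", {
  cfg <- cohort_config(n = 800, feature_betas = c(ODI4 = log(1.5)),
                       seed = 103)
  coh <- generate_cohort(cfg)$participants
  coh <- apply_inclusion(coh)$cohort
  zfun <- function(x) (x - mean(x)) / sd(x)

  d1 <- coh; d1$z <- zfun(d1$ODI4)
  d2 <- coh; d2$time_y <- d2$time_y * 365.25; d2$z <- zfun(d2$ODI4)
  d3 <- coh; d3$z <- zfun(2 * d3$ODI4)
  h <- vapply(list(d1, d2, d3), function(d) fit_cox(d, "ODI4", "all")$hr,
              numeric(1))
  expect_equal(h[2], h[1], tolerance = 1e-6)
  expect_equal(h[3], h[1], tolerance = 1e-12)
})

test_that("sex-stratified models drop the sex covariate and subset rows", {
  cfg <- cohort_config(n = 600, feature_betas = c(ODI4 = log(1.4)),
                       seed = 107)
  coh <- apply_inclusion(generate_cohort(cfg)$participants)$cohort
  coh$z <- (coh$ODI4 - mean(coh$ODI4)) / sd(coh$ODI4)
  men <- fit_cox(coh, "ODI4", "men")
  women <- fit_cox(coh, "ODI4", "women")
  expect_equal(men$n + women$n, nrow(coh))
  expect_equal(men$stratum, "men")
})

test_that("the full protocol flags families with BH within stratum", {
  cfg <- cohort_config(n = 1200,
                       feature_betas = c(ODI4 = log(1.8)),
                       baseline_hazard = 0.02, seed = 109)
  coh <- apply_inclusion(generate_cohort(cfg)$participants)$cohort
  res <- associate_features(
    coh, features = c("AHI", "ODI2", "ODI3", "ODI4", "ODI5",
                      "HypoxicBurden", "T90", "SpO2Mean"),
    strata = c("all", "women"))
  expect_setequal(unique(res$stratum), c("all", "women"))
  expect_true(all(is.na(res$p_bh[res$feature == "AHI"])))
  des <- res$feature %in% c("ODI2", "ODI3", "ODI4", "ODI5",
                            "HypoxicBurden") & res$stratum == "all"
  expect_equal(res$p_bh[des], bh_adjust(res$p[des]))
  expect_true(all(res$p_bh >= res$p, na.rm = TRUE))
  expect_true(res$significant[res$feature == "ODI4" &
                                res$stratum == "all"])
  expect_true(all(res$ci_lo <= res$hr & res$hr <= res$ci_hi,
                  na.rm = TRUE))
})
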