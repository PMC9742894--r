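test_that("event-free noise-free config yields a constant baseline trace", {
  nt <- generate_spo2(signal_config(duration_h = 1, event_rate = 0,
                                    noise_sd = 0, seed = 1))
  expect_equal(nt$signal$samples, rep(96, 3600))
  expect_equal(nrow(nt$events), 0L)
  expect_equal(odi(nt$signal, nt$hypnogram, 3), 0)
})

test_that("the generator is bit-reproducible under a fixed seed", {
  cfg <- signal_config(duration_h = 1, event_rate = 15, seed = 99)
  a <- generate_spo2(cfg)
  b <- generate_spo2(cfg)
  expect_identical(a$signal$samples, b$signal$samples)
  expect_identical(a$events, b$events)
  expect_identical(a$hypnogram$stages, b$hypnogram$stages)
})

test_that("noise-free generated events are all recovered as ODI events", {
  nt <- generate_spo2(signal_config(duration_h = 8, event_rate = 20,
                                    depth_mean = 4.6, depth_sd = 0,
                                    noise_sd = 0, seed = 21))
  odi4 <- odi(nt$signal, nt$hypnogram, 4)
  expect_equal(odi4, nt$truth$events_per_sleep_h, tolerance = 1e-10)
  expect_lt(abs(odi4 - 20), 1 + 3 * sqrt(20 * 8) / (8 * 0.95))
})

test_that("realized event counts converge to the configured rate", {
  set.seed(55)
  rates <- vapply(1:25, function(i) {
    nt <- generate_spo2(signal_config(duration_h = 8, event_rate = 15,
                                      noise_sd = 0))
    nt$truth$event_count / 8
  }, numeric(1))
  expect_lt(abs(mean(rates) / 15 - 1), 0.1)
})

test_that("deeper desaturations raise hypoxic burden and T90; more events raise ODI", {
  f <- function(depth, rate, seed) {
    nt <- generate_spo2(signal_config(duration_h = 2, event_rate = rate,
                                      depth_mean = depth, depth_sd = 0.3,
                                      noise_sd = 0.1, seed = seed))
    hb <- suppressWarnings(
      hypoxic_burden(nt$signal, nt$events, nt$hypnogram)$value)
    c(hb = hb,
      t90 = unname(time_below(restrict_to_stage(nt$signal, nt$hypnogram,
                                                "sleep"), 90)),
      odi3 = odi(nt$signal, nt$hypnogram, 3))
  }
  shallow <- rowMeans(vapply(1:6, function(s) f(3, 20, s), numeric(3)))
  deep <- rowMeans(vapply(1:6, function(s) f(8, 20, s + 100), numeric(3)))
  expect_gt(deep["hb"], shallow["hb"])
  expect_gt(deep["t90"], shallow["t90"])

  sparse <- mean(vapply(1:6, function(s) f(4, 8, s + 200)["odi3"],
                        numeric(1)))
  busy <- mean(vapply(1:6, function(s) f(4, 35, s + 300)["odi3"],
                      numeric(1)))
  expect_gt(busy, sparse)
})

test_that("infeasible event packing errors out", {
  expect_error(
    generate_spo2(signal_config(duration_h = 0.5, event_rate = 120,
                                seed = 3)),
    "infeasible")
})

test_that("cohort config validates its inputs", {
  expect_error(cohort_config(n = 0), "positive")
  expect_error(cohort_config(n = 10, censor_time_y = 1, landmark_y = 2),
               "exceed")
  cfg <- cohort_config(n = 10, feature_betas = c(NotAFeature = 1),
                       seed = 1)
  expect_error(generate_cohort(cfg), "unknown feature name")
})

test_that("null feature effects leave the outcome independent of features", {
  cfg <- cohort_config(n = 3000, feature_betas = c(ODI4 = 0),
                       covariate_betas = c(age = 0, bmi = 0,
                                           race_other = 0,
                                           smoking_ever = 0, female = 0),
                       seed = 42)
  coh <- generate_cohort(cfg)$participants
  r <- suppressWarnings(
    cor.test(coh$ODI4, as.numeric(coh$cvd_event), method = "spearman",
             exact = FALSE))
  expect_gt(r$p.value, 0.001)
})

test_that("the survival generator reproduces the configured hazard ratio", {
  cfg <- cohort_config(n = 6000, feature_betas = c(ODI4 = log(2)),
                       covariate_betas = c(age = 0, bmi = 0,
                                           race_other = 0,
                                           smoking_ever = 0, female = 0),
                       baseline_hazard = 0.02, seed = 77)
  coh <- generate_cohort(cfg)$participants
  z <- scale(coh$ODI4)[, 1]
  hi <- z > 1; lo <- z < -1                 # strata ~2 SD apart
  rate_hi <- sum(coh$cvd_event[hi]) / sum(coh$followup_y[hi])
  rate_lo <- sum(coh$cvd_event[lo]) / sum(coh$followup_y[lo])
  emp <- rate_hi / rate_lo
  expected <- exp(log(2) * (mean(z[hi]) - mean(z[lo])))
  expect_lt(abs(log(emp) - log(expected)), 0.25)
})

test_that("signals mode attaches one reproducible night per participant", {
  cfg <- cohort_config(n = 4, event_rate_range = c(5, 30), seed = 5)
  sim1 <- generate_cohort(cfg, mode = "signals",
                          signal_config = signal_config(duration_h = 0.5))
  sim2 <- generate_cohort(cfg, mode = "signals",
                          signal_config = signal_config(duration_h = 0.5))
  expect_length(sim1$nights, 4L)
  expect_identical(sim1$nights[[3]]$signal$samples,
                   sim2$nights[[3]]$signal$samples)
  expect_equal(sim1$participants$AHI,
               vapply(sim1$nights, function(n) n$truth$events_per_sleep_h,
                      numeric(1)))
})
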