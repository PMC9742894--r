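test_that("cleaning passes an in-range trace through untouched", {
  x <- rep(96, 3600)
  s <- clean_signal(x, 1)
  expect_equal(s$samples, x)
  expect_true(all(s$valid))
})

test_that("cleaning interpolates short artifact runs and keeps long ones invalid", {
  raw <- rep(96, 3600)
  raw[50] <- 0
  s <- clean_signal(raw, 1, max_gap_s = 30)
  expect_equal(s$samples[50], 96)
  expect_true(s$valid[50])

  raw <- rep(96, 3600)
  raw[1001:1600] <- 0                     # 10-min dropout
  s <- clean_signal(raw, 1, max_gap_s = 30)
  expect_false(any(s$valid[1001:1600]))
  expect_equal(mean(s$valid), (3600 - 600) / 3600)
})

test_that("cleaning never changes a sample that was already valid and in range", {
  set.seed(101)
  for (rep in 1:20) {
    raw <- rnorm(500, 95, 2)
    raw[sample(500, 30)] <- sample(c(0, 20, 101, 200), 30, replace = TRUE)
    ok <- raw >= 50 & raw <= 100
    s <- clean_signal(raw, 1)
    expect_identical(s$samples[ok], raw[ok])
    expect_true(all(s$valid[ok]))
  }
})

test_that("cleaning rejects empty and all-artifact input", {
  expect_error(clean_signal(numeric(0), 1), "empty")
  expect_error(clean_signal(rep(0, 100), 1), "no valid samples")
})

test_that("resampling block-averages valid samples", {
  s <- oximetry_signal(rep(95, 100), 1)
  r <- resample_signal(s, 0.2)
  expect_equal(r$samples, rep(95, 20))
  expect_equal(r$rate, 0.2)

  s <- oximetry_signal(c(90, 92, 94, 96, 98), 1)
  expect_equal(resample_signal(s, 0.2)$samples, 94)

  s <- oximetry_signal(rep(c(90, 100), 5), 1)
  expect_equal(resample_signal(s, 0.5)$samples, rep(95, 5))
})

test_that("resampling is the identity at equal rate and invalidates empty windows", {
  s <- oximetry_signal(rnorm(50, 95), 1)
  expect_identical(resample_signal(s, 1), s)

  x <- rep(96, 10)
  v <- c(rep(TRUE, 5), rep(FALSE, 5))
  s <- oximetry_signal(replace(x, !v, NA), 1, v)
  r <- resample_signal(s, 0.2)
  expect_equal(r$valid, c(TRUE, FALSE))
  expect_true(is.na(r$samples[2]))
})

test_that("stage restriction invalidates out-of-stage samples only", {
  hyp <- hypnogram(rep(c("N2", "REM"), each = 60), 30)  # 30 min each
  s <- clean_signal(rep(96, 3600), 1)
  all_sleep <- restrict_to_stage(s, hyp, c("NREM", "REM"))
  expect_equal(all_sleep$valid, s$valid)

  rem <- restrict_to_stage(s, hyp, "REM")
  expect_false(any(rem$valid[1:1800]))
  expect_true(all(rem$valid[1801:3600]))
  expect_equal(tst_hours(hyp, "REM"), 0.5)
  expect_error(restrict_to_stage(s, hyp, character(0)), "empty stage set")
})

test_that("stage-restricted features equal features on manually cut segments", {
  set.seed(7)
  x <- rnorm(3600, 95, 1.5)
  hyp <- hypnogram(rep(c("N2", "REM", "N3", "REM"), each = 30), 30)
  s <- clean_signal(pmin(x, 100), 1)
  rem <- restrict_to_stage(s, hyp, "REM")
  rem_idx <- c(901:1800, 2701:3600)
  manual <- clean_signal(s$samples[rem_idx], 1)
  expect_equal(unname(distribution_moments(rem)),
               unname(distribution_moments(manual)))
  expect_equal(unname(time_below(rem)), unname(time_below(manual)))
})

test_that("respiratory events are sorted and overlaps merged", {
  ev <- respiratory_events(c(100, 50, 70), c(30, 25, 20),
                           c("hypopnea", "obstructive-apnea", "hypopnea"))
  expect_equal(ev$onset, c(50, 100))
  expect_equal(ev$duration, c(40, 30))        # 50-75 and 70-90 merge
  expect_error(respiratory_events(1, -5), "positive")
  expect_error(respiratory_events(1, 10, "snore"), "unknown event kind")
})

test_that("CSV readers round-trip signal, hypnogram and events", {
  tmp <- withr::local_tempdir()
  spo2 <- file.path(tmp, "s.csv")
  write.csv(data.frame(time_s = 0:99, spo2 = rep(96, 100)), spo2,
            row.names = FALSE)
  s <- read_spo2_csv(spo2)
  expect_equal(s$rate, 1)
  expect_equal(s$samples, rep(96, 100))

  hf <- file.path(tmp, "h.csv")
  write.csv(data.frame(epoch = 1:4, stage = c("WAKE", "N2", "REM", "N2")),
            hf, row.names = FALSE)
  h <- read_hypnogram_csv(hf)
  expect_equal(h$stages, c("WAKE", "N2", "REM", "N2"))

  ef <- file.path(tmp, "e.csv")
  write.csv(data.frame(onset_s = c(10, 50), duration_s = c(20, 15),
                       kind = "hypopnea"), ef, row.names = FALSE)
  expect_equal(read_events_csv(ef)$onset, c(10, 50))
})
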