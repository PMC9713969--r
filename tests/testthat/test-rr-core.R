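test_that("rr_series derives cumulative time and validates intervals", {
  s <- rr_series(c(800, 820, 790))
  expect_equal(s$t_cum, c(0.80, 1.62, 2.41))
  expect_equal(length(s), 3L)
  expect_error(rr_series(numeric(0)), class = "wd_empty_input_error")
  expect_error(rr_series(c(800, -5)), class = "wd_format_error")
})

test_that("read_rr parses both dialects and reports bad lines", {
  p <- write_rr_file(c("# warmup", "800", "820", "790"))
  s <- read_rr(p)
  expect_equal(s$intervals, c(800, 820, 790))
  expect_equal(s$meta$source, basename(p))

  csv <- tempfile(fileext = ".csv")
  writeLines(c("time_s,rr_ms", "0.8,800", "1.62,820"), csv)
  s2 <- read_rr(csv)
  expect_equal(s2$intervals, c(800, 820))
  expect_equal(s2$t_cum, c(0.8, 1.62))

  bad <- write_rr_file(c("800", "abc"))
  expect_error(read_rr(bad), "line 2", class = "wd_format_error")
  empty <- write_rr_file(character(0))
  expect_error(read_rr(empty), class = "wd_empty_input_error")
  expect_error(read_rr(tempfile()), class = "wd_io_error")
})

test_that("mean heart rate is the rate of the mean interval", {
  expect_equal(mean_heart_rate(rr_series(rep(800, 10))), 75)
  # not the mean of instantaneous rates
  expect_equal(mean_heart_rate(rr_series(c(600, 1000))), 75)
})

test_that("fixture PRE-light heart rates pass through to the printed mean", {
  hr <- fixture_values(study_fixture(), "hr", "light", "PRE")
  expect_equal(round(mean(hr)), 135)
  expect_equal(round(sd(hr)), 15)
})

test_that("segment extraction keeps beats by end time in a half-open window", {
  s <- generate_fractal_rr(1.0, 1000, mean_rr = 800, sd_rr = 30, seed = 9)
  seg <- extract_segment(s, 360, 480)
  # direct-scan oracle on the same times
  expect_equal(length(seg), sum(s$t_cum >= 360 & s$t_cum < 480))
  expect_gte(min(s$t_cum[s$t_cum >= 360]), 360)
  # ~150 beats for 2 min at 75 bpm
  expect_gt(length(seg), 130)
  expect_lt(length(seg), 170)
  # interval values carried bit-exactly
  expect_identical(seg$intervals, s$intervals[s$t_cum >= 360 & s$t_cum < 480])
  # identity window: [0, duration) keeps every beat but the one ending
  # exactly at the boundary, so query just past it
  full <- extract_segment(s, 0, duration(s) + 1e-9)
  expect_identical(full$intervals, s$intervals)
  expect_error(extract_segment(s, 500, 400), class = "wd_parameter_error")
  expect_error(extract_segment(s, 360, 1e5), "available",
               class = "wd_coverage_error")
})

test_that("artifact screening is a fixed point on clean series and finds injections", {
  clean <- generate_fractal_rr(1.0, 600, mean_rr = 800, sd_rr = 40, seed = 1)
  r0 <- detect_and_correct_artifacts(clean)
  expect_equal(r0$report$corrected_count, 0L)
  expect_false(r0$report$excluded)
  expect_identical(r0$series$intervals, clean$intervals)

  # 10 ectopic pairs in 600 beats
  inj <- inject_artifacts(clean, kinds = "ectopic", rate = 10 / 600, seed = 21)
  r <- detect_and_correct_artifacts(inj$series)
  expect_gte(r$report$percent_corrected, 1.5)
  expect_lte(r$report$percent_corrected, 3.5)
  expect_false(r$report$excluded)
  flagged <- which(r$report$flags == "suspect")
  expect_gte(mean(inj$truth %in% flagged), 0.8)
  # corrected values return to the physiological neighbourhood
  expect_true(all(abs(r$series$intervals[inj$truth] - 800) < 200))
  # idempotence: second pass finds nothing left to correct
  expect_equal(detect_and_correct_artifacts(r$series)$report$corrected_count, 0L)

  # heavy contamination crosses the exclusion threshold
  inj8 <- inject_artifacts(clean, rate = 0.08, seed = 22)
  r8 <- detect_and_correct_artifacts(inj8$series)
  expect_true(r8$report$excluded)
  expect_gt(r8$report$percent_corrected, 5)

  expect_error(detect_and_correct_artifacts(rr_series(rep(800, 5))),
               class = "wd_insufficient_data_error")
})

test_that("exclusion flips exactly at the configured threshold", {
  # rule is strict inequality against the threshold
  clean <- generate_fractal_rr(1.0, 200, seed = 5)
  cfg0 <- preprocess_config(artifact_threshold_pct = 0)
  r <- detect_and_correct_artifacts(clean, cfg0)
  expect_identical(r$report$excluded, r$report$percent_corrected > 0)
  cfg <- preprocess_config(artifact_threshold_pct = 5)
  inj <- inject_artifacts(clean, kinds = "ectopic", rate = 0.06, seed = 2)
  r2 <- detect_and_correct_artifacts(inj$series, cfg)
  expect_identical(r2$report$excluded, r2$report$percent_corrected > 5)
})

test_that("smoothness-priors detrending matches a dense solve and preserves the mean", {
  # constant series is a fixed point
  const <- rr_series(rep(800, 100))
  expect_equal(smoothness_priors_detrend(const, 500)$intervals, rep(800, 100),
               tolerance = 1e-9)
  # slow linear drift is removed almost entirely
  drift <- rr_series(seq(700, 900, length.out = 500))
  dd <- smoothness_priors_detrend(drift, 500)
  expect_lt(sd(dd$intervals), 0.1 * sd(drift$intervals))
  expect_equal(mean(dd$intervals), mean(drift$intervals), tolerance = 1e-9)
  # white noise passes nearly unchanged
  set.seed(5)
  wn <- rr_series(rnorm(500, 800, 30))
  dw <- smoothness_priors_detrend(wn, 500)
  expect_gt(cor(wn$intervals, dw$intervals), 0.95)
  # dense-matrix oracle
  z <- wn$intervals[1:120]
  expect_equal(smoothness_priors_detrend(rr_series(z), 500)$intervals,
               z - naive_sp_trend(z, 500) + mean(z), tolerance = 1e-8)
  # linearity of the trend operator after mean handling
  d1 <- smoothness_priors_detrend(rr_series(z), 300)$intervals - mean(z)
  d2 <- smoothness_priors_detrend(rr_series(2 * z), 300)$intervals - mean(2 * z)
  expect_equal(d2, 2 * d1, tolerance = 1e-8)
  expect_error(smoothness_priors_detrend(wn, -1), class = "wd_parameter_error")
  expect_error(smoothness_priors_detrend(rr_series(c(800, 810)), 500),
               class = "wd_insufficient_data_error")
})
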