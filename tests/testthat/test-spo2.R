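test_that("ratio of ratios follows its arithmetic definition", {
  expect_equal(ratio_of_ratios(1, 1, 1, 1), 1)
  expect_equal(ratio_of_ratios(2, 100, 4, 100), 0.5)
  expect_equal(ratio_of_ratios(30, 5000, 150, 6000), 0.24)
  expect_message(
    r <- ratio_of_ratios(c(1, 1), c(1, 0), c(1, 1), c(1, 1)),
    "masked 1"
  )
  expect_true(is.na(r[2]))
})

test_that("linear calibration maps R to percent saturation", {
  expect_identical(calibrate_spo2(0), 104)
  expect_equal(calibrate_spo2(4 / 17), 100)
  expect_identical(calibrate_spo2(1), 87)
  # slope is -17 exactly, monotone decreasing
  r <- seq(0, 2, by = 0.01)
  expect_equal(diff(calibrate_spo2(r)) / diff(r), rep(-17, length(r) - 1))
  expect_equal(calibrate_spo2(c(-0.5, 10), clip = TRUE), c(100, 0))
})

test_that("extraction recovers injected plateaus from noiseless recordings", {
  p <- subject_params(noise_sd = 0, seed = 3)
  tr <- data.frame(time_s = (0:23999) / 100,
                   spo2 = c(rep(98, 12000), rep(90, 12000)))
  s <- extract_spo2(simulate_from_trajectory(tr, p, "ear"))
  m1 <- mean(s$spo2[s$time_s > 10 & s$time_s < 110])
  m2 <- mean(s$spo2[s$time_s > 130 & s$time_s < 230])
  expect_equal(m1, 98, tolerance = 0.5 / 98)
  expect_equal(m2, 90, tolerance = 0.5 / 90)
})

test_that("noiseless generation encodes the inverse calibration exactly", {
  p <- subject_params(noise_sd = 0, seed = 11)
  s <- extract_spo2(simulate_from_trajectory(flat_trajectory(97), p, "ear"))
  sel <- s$time_s > 15 & s$time_s < 105
  # per-beat R from the generated envelopes and the configured DC levels
  r_gen <- (s$ac_red[sel] / 25000) / (s$ac_ir[sel] / 50000)
  expect_lt(max(abs(r_gen - 7 / 17)), 1e-6)
  # the full chain (with estimated DC baselines) stays within 0.3% SpO2
  expect_lt(max(abs(calibrate_spo2(s$r[sel]) - 97)), 0.3)
})

test_that("SpO2 is invariant to channel gain when thresholds scale with it", {
  p <- subject_params(noise_sd = 0, seed = 21)
  rec <- simulate_from_trajectory(flat_trajectory(96), p, "ear")
  k <- 3.7
  rec_scaled <- ppg_recording(
    time_s = rec$time_s, red = k * rec$red, infrared = rec$infrared,
    button = rec$button, fs = recording_fs(rec),
    subject_id = "S01", site = "ear"
  )
  cfg <- spo2_config()
  cfg_scaled <- spo2_config(prominence_red = k * cfg$prominence_red)
  s1 <- extract_spo2(rec, cfg)
  s2 <- extract_spo2(rec_scaled, cfg_scaled)
  expect_equal(s1$spo2, s2$spo2, tolerance = 1e-9)
})

test_that("an unusable channel fails at the extrema stage, naming the channel", {
  n <- 12000
  t <- (seq_len(n) - 1) / 100
  rec <- ppg_recording(time_s = t, red = 25000 + 100 * sin(2 * pi * 1.2 * t),
                       infrared = rep(50000, n), button = rep(0, n),
                       fs = 100, subject_id = "S01", site = "ear")
  expect_error(extract_spo2(rec), regexp = "infrared",
               class = "earox_degenerate_signal")
})

test_that("heart rate is the median inter-peak rate", {
  expect_equal(estimate_heart_rate(seq(0, 10, by = 0.5)), 120)
  expect_equal(estimate_heart_rate(seq(0, 10, by = 1)), 60)
  withr::with_seed(5, {
    gaps <- 0.8 + runif(60, -0.05, 0.05)
    peaks <- cumsum(c(0, gaps))
    oracle <- 60 / median(gaps)
    expect_equal(estimate_heart_rate(peaks), oracle)
    expect_equal(estimate_heart_rate(peaks), 75, tolerance = 2 / 75)
  })
  expect_error(estimate_heart_rate(1), class = "earox_degenerate_signal")
})

test_that("config files override defaults and reject unknown keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("prominence_ir: 220", "clip: yes"), path)
  cfg <- read_spo2_config(path)
  expect_equal(cfg$prominence_ir, 220)
  expect_true(cfg$clip)
  expect_equal(cfg$prominence_red, 30)
  writeLines("not_a_key: 1", path)
  expect_error(read_spo2_config(path), class = "earox_config_error")
})
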