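fs <- 100

# spo2_series with Gaussian dips at given trough times
dip_series <- function(trough_times, depth = 8, tau = 6, duration = 435,
                       resting = 97) {
  t <- (seq_len(duration * fs) - 1) / fs
  s <- rep(resting, length(t))
  for (tm in trough_times) s <- s - depth * exp(-((t - tm) / tau)^2 / 2)
  as_spo2_series(data.frame(time_s = t, spo2 = s), fs = fs)
}

test_that("button segments are recovered exactly, glitches and all", {
  n <- 40000
  b <- rep(0, n)
  b[12001:14500] <- 1 # 120-145 s
  b[20501:23000] <- 1
  b[29001:31500] <- 1
  ev <- segment_breath_holds(b, fs = fs)
  expect_identical(nrow(ev), 3L)
  expect_equal(ev$press_time_s, c(120, 205, 290), tolerance = 1.01 / fs)
  expect_equal(ev$release_time_s, c(145, 230, 315), tolerance = 1.01 / fs)

  expect_identical(nrow(segment_breath_holds(rep(0, 1000), fs = fs)), 0L)

  # isolated single-sample spikes must not create or split events
  b2 <- b
  b2[c(5000, 16000, 35000)] <- 1
  b2[13000] <- 0
  ev2 <- segment_breath_holds(b2, fs = fs)
  expect_equal(ev2, ev)
  oracle <- brute_force_events(b2, fs)
  expect_equal(ev2$press_time_s, oracle$press)
  expect_equal(ev2$release_time_s, oracle$release)

  expect_warning(segment_breath_holds(c(rep(0, 500), rep(1, 500)), fs = fs),
                 "record end")
  expect_error(segment_breath_holds(c(0, 1, 2), fs = fs),
               class = "earox_format_error")
})

test_that("first-trough search finds the dip at its true lag", {
  release <- 145
  s5 <- dip_series(release + 5)
  expect_equal(find_spo2_trough(s5, release), release + 5, tolerance = 0.2 / 150)

  s0 <- dip_series(release)
  expect_equal(find_spo2_trough(s0, release) - release, 0, tolerance = 0.2)

  # two dips inside the window: the earlier one wins
  s2 <- dip_series(c(release + 4, release + 15), tau = 3)
  expect_equal(find_spo2_trough(s2, release), release + 4, tolerance = 0.2 / 149)

  # nothing prominent -> missing
  expect_true(is.na(find_spo2_trough(dip_series(numeric(0)), release)))
})

test_that("per-subject delays, ranges and the relative delay are assembled correctly", {
  events <- tibble::tibble(hold = 1:3, press_time_s = c(120, 205, 290),
                           release_time_s = c(145, 230, 315))
  ear <- dip_series(events$release_time_s + 4.35)
  fin <- dip_series(events$release_time_s + 16.75)
  d <- compute_delays(events, ear, fin)
  g <- glance(d)
  expect_equal(g$mean_delay_ear_s, 4.35, tolerance = 0.3 / 4.35)
  expect_equal(g$mean_delay_finger_s, 16.75, tolerance = 0.3 / 16.75)
  expect_equal(g$relative_delay_s, 12.4, tolerance = 0.5 / 12.4)
  # identity: relative = finger mean - ear mean, exactly
  expect_identical(g$relative_delay_s, g$mean_delay_finger_s - g$mean_delay_ear_s)

  same <- compute_delays(events, ear, ear)
  expect_equal(glance(same)$relative_delay_s, 0, tolerance = 0.3)

  # per-hold delays {4, 5, 6} -> mean 5, range 2
  staggered <- dip_series(events$release_time_s + c(4, 5, 6), tau = 4)
  ds <- compute_delays(events, staggered, fin)
  expect_equal(glance(ds)$mean_delay_ear_s, 5, tolerance = 0.05)
  expect_equal(glance(ds)$range_ear_s, 2, tolerance = 0.1)
})

test_that("delaying a trace shifts its estimated delay equivariantly", {
  events <- tibble::tibble(hold = 1:3, press_time_s = c(120, 205, 290),
                           release_time_s = c(145, 230, 315))
  base <- dip_series(events$release_time_s + 6)
  shift <- 2.5
  shifted <- dip_series(events$release_time_s + 6 + shift)
  d0 <- compute_delays(events, base, base)
  d1 <- compute_delays(events, base, shifted)
  expect_equal(glance(d1)$mean_delay_finger_s - glance(d0)$mean_delay_finger_s,
               shift, tolerance = 1.5 / fs)
})

test_that("missing troughs are handled per the exclusion rules", {
  events <- tibble::tibble(hold = 1:2, press_time_s = c(120, 205),
                           release_time_s = c(145, 230))
  ear <- dip_series(c(145 + 4, 230 + 5))
  flat <- dip_series(numeric(0))
  expect_error(compute_delays(events, ear, flat),
               class = "earox_degenerate_signal")
  # one of two finger dips missing: mean over the remaining hold
  fin <- dip_series(145 + 10)
  expect_message(d <- compute_delays(events, ear, fin), "excluded")
  expect_equal(glance(d)$mean_delay_finger_s, 10, tolerance = 0.05)
})
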