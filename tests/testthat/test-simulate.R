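test_that("trajectories place desaturation troughs exactly at hold end + delay", {
  tl <- make_protocol()
  p <- subject_params(seed = 1)
  traj <- build_spo2_trajectory(tl, p, "ear")
  expect_equal(attr(traj, "trough_times_s"), c(145, 230, 315) + 4.35)

  p2 <- subject_params(
    ear = site_params(transit_delay = 2.2),
    finger = site_params(ac_amplitude = 540, transit_delay = 9.9)
  )
  t_e <- attr(build_spo2_trajectory(tl, p2, "ear"), "trough_times_s")
  t_f <- attr(build_spo2_trajectory(tl, p2, "finger"), "trough_times_s")
  expect_equal(t_f - t_e, rep(9.9 - 2.2, 3))

  # zero depth -> flat trace at the resting level
  p0 <- subject_params(ear = site_params(desat_depth = 0))
  flat <- build_spo2_trajectory(tl, p0, "ear")
  expect_equal(unique(flat$spo2), 97)

  # per-sample minimum sits at the announced trough time
  idx <- which.min(traj$spo2[traj$time_s < 200])
  expect_equal(traj$time_s[idx], 149.35, tolerance = 0.011)

  p_deep <- subject_params(resting_spo2 = 55,
                           ear = site_params(desat_depth = 20))
  expect_warning(cl <- build_spo2_trajectory(tl, p_deep, "ear"), "floor")
  expect_gte(min(cl$spo2), 50)
})

test_that("simulation is bit-deterministic under a fixed seed", {
  p <- subject_params(seed = 123)
  a <- simulate_subject(p)
  b <- simulate_subject(p)
  expect_identical(a$recordings$ear$infrared, b$recordings$ear$infrared)
  expect_identical(a$recordings$finger$red, b$recordings$finger$red)

  c1 <- suppressMessages(simulate_cohort(3, base_seed = 9))
  c2 <- suppressMessages(simulate_cohort(3, base_seed = 9))
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$recordings$recording[[1]]$red,
                   c2$recordings$recording[[1]]$red)
})

test_that("generated resting peak-to-peak equals twice the AC amplitude", {
  p <- subject_params(noise_sd = 0, drift_amplitude = 0,
                      respiration_mod_depth = 0, seed = 5)
  rec <- simulate_from_trajectory(flat_trajectory(97, duration = 60), p, "ear")
  pp_ir <- diff(range(rec$infrared[1000:5000]))
  expect_equal(pp_ir, 2 * 230, tolerance = 0.02)
})

test_that("default finger/ear amplitude contrast is recovered from the envelopes", {
  p <- subject_params(noise_sd = 0, seed = 8)
  tr <- flat_trajectory(97)
  s_ear <- extract_spo2(simulate_from_trajectory(tr, p, "ear"))
  s_fin <- extract_spo2(simulate_from_trajectory(tr, p, "finger"))
  sel <- s_ear$time_s > 15 & s_ear$time_s < 105
  ratio <- mean(s_fin$ac_ir[sel]) / mean(s_ear$ac_ir[sel])
  expect_equal(ratio, 2.35, tolerance = 0.05 / 2.35)
})

test_that("cohorts are balanced, logged, and sized as requested", {
  co <- suppressMessages(simulate_cohort(14, base_seed = 2))
  expect_identical(nrow(co$truth), 14L)
  expect_identical(sum(co$truth$sex == "F"), 7L)
  expect_identical(sum(co$truth$sex == "M"), 7L)
  expect_identical(nrow(co$recordings), 28L)

  expect_message(one <- simulate_cohort(1, base_seed = 4), "default parameter")
  expect_identical(nrow(one$truth), 1L)

  expect_error(simulate_cohort(0), class = "earox_config_error")
  expect_error(simulate_subject(subject_params(), fs = 10),
               class = "earox_config_error")
  expect_error(suppressMessages(simulate_cohort(2, param_ranges = list(bogus = c(0, 1)))),
               class = "earox_config_error")
})
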