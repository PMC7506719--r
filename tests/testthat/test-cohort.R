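series_from <- function(t, y) as_spo2_series(data.frame(time_s = t, spo2 = y))

test_that("resting SpO2 averages the pre-press window only", {
  t <- (0:19999) / 100 # 200 s
  expect_equal(resting_spo2(series_from(t, rep(98, length(t))), 120), 98)

  y <- ifelse(t < 120, 96, 90)
  expect_equal(resting_spo2(series_from(t, y), 120), 96, tolerance = 1e-3)

  # linear 95 -> 97 across the window averages to 96
  y2 <- ifelse(t < 60, 95, ifelse(t <= 120, 95 + 2 * (t - 60) / 60, 97))
  expect_equal(resting_spo2(series_from(t, y2), 120), 96, tolerance = 1e-3)

  expect_error(resting_spo2(series_from(t, y), first_press = 30),
               class = "earox_config_error")
})

test_that("site difference summary matches hand-computed values", {
  same <- site_difference_summary(c(96, 97, 98), c(96, 97, 98))
  expect_equal(same$rms_diff, 0)
  expect_equal(same$mean_diff, 0)

  plus1 <- site_difference_summary(c(96, 97, 98) + 1, c(96, 97, 98))
  expect_equal(plus1$rms_diff, 1)
  expect_equal(plus1$mean_diff, 1)

  mixed <- site_difference_summary(c(97, 96), c(96, 97)) # diffs {1, -1}
  expect_equal(mixed$rms_diff, 1)
  expect_equal(mixed$mean_diff, 0)

  expect_error(site_difference_summary(1:3, 1:2), class = "earox_format_error")
})

test_that("rms difference dominates the absolute mean difference", {
  withr::with_seed(31, {
    for (i in 1:20) {
      e <- rnorm(10, 97, 1)
      f <- rnorm(10, 97, 1)
      s <- site_difference_summary(e, f)
      expect_gte(s$rms_diff + 1e-12, abs(s$mean_diff))
    }
  })
})

test_that("healthy-range agreement uses the closed 94-100 interval", {
  expect_equal(healthy_range_agreement(c(95, 96, 94), c(97, 98, 100)), 1)
  expect_equal(healthy_range_agreement(c(93, 95), c(95, 95)), 0.5)
  expect_equal(healthy_range_agreement(c(92, 93), c(93, 92)), 1) # both out: agree
  expect_equal(healthy_range_agreement(94, 94), 1) # boundary included
})

test_that("amplitude normalisation pins the cohort maximum at one", {
  single <- amplitude_summary(tibble::tibble(
    subject_id = "S01", amp_ear = 300, amp_finger = 700))
  expect_equal(max(single$per_subject$norm_amp_finger), 1)
  expect_true(all(c(single$per_subject$norm_amp_ear,
                    single$per_subject$norm_amp_finger) <= 1))
  expect_equal(single$amp_ratio_mean, 700 / 300)

  twin <- amplitude_summary(tibble::tibble(
    subject_id = c("A", "B"), amp_ear = c(200, 200), amp_finger = c(470, 470)))
  expect_equal(twin$per_subject$norm_amp_ear[1], twin$per_subject$norm_amp_ear[2])
  expect_equal(twin$amp_ratio_mean, 2.35)

  expect_warning(
    dropped <- amplitude_summary(tibble::tibble(
      subject_id = c("A", "B"), amp_ear = c(200, 0), amp_finger = c(470, 400))),
    "degenerate")
  expect_identical(nrow(dropped$per_subject), 1L)
})

test_that("group t-test behaves at its reference points", {
  same <- group_ttest(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  withr::with_seed(77, {
    a <- rnorm(4, 0, 0.01)
    b <- rnorm(4, 10, 0.01)
    res <- group_ttest(a, b)
    # closed-form Welch t oracle
    t_oracle <- (mean(a) - mean(b)) / sqrt(var(a) / 4 + var(b) / 4)
    expect_equal(res$statistic, t_oracle)
    expect_lt(res$p_value, 0.001)
  })

  x <- c(1, 2, 3, 4)
  expect_error(group_ttest(x, x + 2, paired = TRUE),
               class = "earox_degenerate_signal")
  expect_error(group_ttest(1, c(1, 2)), class = "earox_config_error")
})

test_that("pearson correlation matches hand-computed values", {
  x <- c(1, 2, 3)
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_equal(pearson(x, c(1, 3, 2))$r, 0.5)
  expect_error(pearson(c(1, 2), c(3, 4)), class = "earox_config_error")
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)),
               class = "earox_degenerate_signal")
})

test_that("cohort summary degrades gracefully for tiny cohorts", {
  row <- tibble::tibble(
    subject_id = "S01", sex = "F", age = 25,
    resting_spo2_ear = 96.5, resting_spo2_finger = 96.2,
    amp_ear = 300, amp_finger = 700,
    mean_delay_ear = 4.1, mean_delay_finger = 15.9,
    range_ear = 1, range_finger = 2, relative_delay = 11.8, heart_rate = 68)
  expect_warning(s1 <- suppressMessages(summarize_cohort(row)),
                 "single-subject")
  expect_equal(s1$scalars$rms_site_diff, 0.3, tolerance = 1e-9)
  expect_true(all(is.na(s1$tests$p_value)))

  expect_warning(s0 <- summarize_cohort(row[0, ]), "empty")
  expect_identical(s0$scalars$n_subjects, 0L)
  expect_identical(nrow(s0$tests), 0L)
})
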