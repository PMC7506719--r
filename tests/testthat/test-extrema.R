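fs <- 100

test_that("sinusoid peaks and troughs are counted and prominence-gated", {
  t <- (0:999) / fs # 10 s
  x <- 200 * sin(2 * pi * 2 * t)
  ext <- detect_extrema(x, fs, min_prominence = 150)
  expect_true(abs(nrow(ext$peaks) - 20) <= 1)
  expect_true(abs(nrow(ext$troughs) - 20) <= 1)
  expect_equal(unique(round(ext$peaks$value)), 200)

  none <- detect_extrema(x, fs, min_prominence = 500)
  expect_identical(nrow(none$peaks), 0L)
  expect_identical(nrow(none$troughs), 0L)
})

test_that("prominence detection matches the brute-force definition exactly", {
  t <- (0:2999) / fs # 30 s two-tone
  x <- 100 * sin(2 * pi * 1.5 * t) + 80 * sin(2 * pi * 0.2 * t)
  for (thr in c(10, 60, 150)) {
    fast <- detect_extrema(x, fs, thr)
    slow_p <- brute_force_peaks(x, thr)
    slow_t <- brute_force_peaks(-x, thr)
    expect_identical(fast$peaks$index, slow_p$index)
    expect_equal(fast$peaks$prominence, slow_p$prominence)
    expect_identical(fast$troughs$index, slow_t$index)
    expect_equal(fast$troughs$prominence, slow_t$prominence)
  }
})

test_that("prominence equivalence holds across randomised signals", {
  withr::with_seed(99, {
    for (rep in 1:5) {
      f1 <- runif(1, 0.8, 3)
      f2 <- runif(1, 0.05, 0.4)
      t <- (0:1499) / fs
      x <- runif(1, 50, 150) * sin(2 * pi * f1 * t) +
        runif(1, 20, 120) * sin(2 * pi * f2 * t + runif(1, 0, 6)) +
        rnorm(1500, 0, 5)
      thr <- runif(1, 5, 80)
      fast <- detect_extrema(x, fs, thr)
      slow <- brute_force_peaks(x, thr)
      expect_identical(fast$peaks$index, slow$index)
      expect_equal(fast$peaks$prominence, slow$prominence)
    }
  })
})

test_that("AC envelope reproduces analytic peak-to-peak amplitudes", {
  t <- (0:5999) / fs # 60 s
  x <- sin(2 * pi * 1.5 * t)
  env <- ac_envelope(detect_extrema(x, fs, 0.5), t)
  mid <- 500:5500
  expect_equal(env$ac_amplitude[mid], rep(2, length(mid)), tolerance = 0.02)

  # AM envelope: (1 + 0.5 sin(2 pi 0.1 t)) carrier -> pp = 2 (1 + 0.5 sin)
  am <- (1 + 0.5 * sin(2 * pi * 0.1 * t)) * sin(2 * pi * 1.5 * t)
  enva <- ac_envelope(detect_extrema(am, fs, 0.2), t)
  target <- 2 * (1 + 0.5 * sin(2 * pi * 0.1 * t))
  expect_equal(enva$ac_amplitude[mid], target[mid], tolerance = 0.05 * 2)
})

test_that("degenerate channels fail with an identifying error", {
  t <- (0:999) / fs
  ext <- detect_extrema(rep(0, 1000), fs, 1)
  expect_error(ac_envelope(ext, t, channel = "infrared"),
               regexp = "infrared", class = "earox_degenerate_signal")
  expect_error(detect_extrema(rnorm(100), fs, min_prominence = 0),
               class = "earox_config_error")
})
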