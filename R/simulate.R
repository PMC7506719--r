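#' Per-site simulation parameters
#'
#' @param ac_amplitude Cardiac AC amplitude of the infrared channel, ADC
#'   counts; the generated resting infrared peak-to-peak excursion is
#'   `2 * ac_amplitude`. The finger default is 2.35 times the ear default,
#'   matching the typical finger/ear PPG amplitude ratio.
#' @param dc_level Infrared DC level, ADC counts. The red channel is scaled
#'   to half this DC so that the default prominence thresholds (150 infrared
#'   / 30 red) are simultaneously sensible.
#' @param transit_delay Blood transit delay from the lungs to the site,
#'   seconds: the SpO2 trough lags the breath-hold end by exactly this long.
#' @param desat_depth Depth of the breath-hold desaturation dip, percent.
#' @param desat_tau Time constant of the dip, seconds.
#' @return A list of class `site_params`.
#' @export
site_params <- function(ac_amplitude = 230, dc_level = 50000,
                        transit_delay = 4.35, desat_depth = 8,
                        desat_tau = 6) {
  p <- list(ac_amplitude = ac_amplitude, dc_level = dc_level,
            transit_delay = transit_delay, desat_depth = desat_depth,
            desat_tau = desat_tau)
  if (ac_amplitude <= 0 || dc_level <= 0) {
    abort_config("ac_amplitude and dc_level must be > 0")
  }
  if (transit_delay < 0 || desat_depth < 0 || desat_tau <= 0) {
    abort_config("transit_delay, desat_depth >= 0 and desat_tau > 0 required")
  }
  structure(p, class = "site_params")
}

#' Ground-truth parameters of one simulated subject
#'
#' Defaults correspond to the typical study conditions: resting SpO2 in the
#' healthy 94-100% range, ear transit delay around 4.35 s and finger delay
#' around 16.75 s, and a finger PPG amplitude 2.35 times the ear amplitude.
#'
#' @param subject_id Identifier string.
#' @param sex `"F"` or `"M"`.
#' @param age Years.
#' @param heart_rate Beats per minute.
#' @param resting_spo2 Baseline saturation, percent (0, 100].
#' @param ear,finger [site_params()] for each site.
#' @param respiration_rate Breathing rate, Hz.
#' @param respiration_mod_depth Fractional respiratory amplitude modulation
#'   of the cardiac AC component, in \[0, 1).
#' @param noise_sd Additive Gaussian noise, ADC counts.
#' @param drift_amplitude Slow sinusoidal baseline drift (period 120 s),
#'   ADC counts on the infrared channel; other channels drift
#'   proportionally to their DC level.
#' @param seed Integer seed making the subject's recording deterministic.
#' @return A list of class `subject_params`.
#' @export
subject_params <- function(subject_id = "S01", sex = c("F", "M"), age = 25,
                           heart_rate = 70, resting_spo2 = 97,
                           ear = site_params(),
                           finger = site_params(ac_amplitude = 2.35 * 230,
                                                transit_delay = 16.75),
                           respiration_rate = 0.25,
                           respiration_mod_depth = 0.15,
                           noise_sd = 2, drift_amplitude = 200, seed = 1L) {
  sex <- match.arg(sex)
  if (resting_spo2 <= 0 || resting_spo2 > 100) {
    abort_config("resting_spo2 must be in (0, 100]")
  }
  if (heart_rate <= 0) abort_config("heart_rate must be > 0")
  if (respiration_mod_depth < 0 || respiration_mod_depth >= 1) {
    abort_config("respiration_mod_depth must be in [0, 1)")
  }
  if (noise_sd < 0 || drift_amplitude < 0) {
    abort_config("noise_sd and drift_amplitude must be >= 0")
  }
  structure(list(
    subject_id = subject_id, sex = sex, age = age, heart_rate = heart_rate,
    resting_spo2 = resting_spo2, ear = ear, finger = finger,
    respiration_rate = respiration_rate,
    respiration_mod_depth = respiration_mod_depth,
    noise_sd = noise_sd, drift_amplitude = drift_amplitude,
    seed = as.integer(seed)
  ), class = "subject_params")
}

#' Ground-truth SpO2 trajectory for one site
#'
#' Builds the noiseless saturation trajectory implied by the protocol: the
#' trace equals `resting_spo2` at rest and dips around each breath hold with
#' a smooth dip of depth `desat_depth` whose minimum falls exactly
#' `transit_delay` seconds after the hold end. The default dip is a
#' symmetric Gaussian bell `depth * exp(-((t - t_min) / tau)^2 / 2)`; the
#' `"exponential"` shape gives an asymmetric exponential fall/recovery with
#' the same time constant (its trough is a slope discontinuity, so smoothed
#' trough times shift slightly early).
#'
#' @param timeline A [make_protocol()] timeline.
#' @param params A [subject_params()] object.
#' @param site `"ear"` or `"finger"`.
#' @param fs Sampling rate of the output grid, Hz.
#' @param shape Dip shape: `"gaussian"` (default) or `"exponential"`.
#'
#' @return A tibble with columns `time_s`, `spo2`; attribute
#'   `trough_times_s` holds the exact per-hold trough times
#'   (`hold_end + transit_delay`). The trajectory is floored at 50% (with a
#'   warning) if the dip depth would take it below that.
#' @export
build_spo2_trajectory <- function(timeline, params, site = c("ear", "finger"),
                                  fs = 100, shape = c("gaussian", "exponential")) {
  site <- match.arg(site)
  shape <- match.arg(shape)
  sp <- params[[site]]
  total <- protocol_duration(timeline)
  n <- round(total * fs)
  t <- (seq_len(n) - 1) / fs
  holds <- hold_times(timeline)
  troughs <- holds$hold_end_s + sp$transit_delay

  dip <- rep(0, n)
  if (nrow(holds) > 0 && sp$desat_depth > 0) {
    for (k in seq_len(nrow(holds))) {
      tm <- troughs[k]
      if (shape == "gaussian") {
        dip <- dip + sp$desat_depth * exp(-((t - tm) / sp$desat_tau)^2 / 2)
      } else {
        te <- holds$exhale_start_s[k]
        fall <- (1 - exp(-(pmax(t, te) - te) / sp$desat_tau)) /
          (1 - exp(-(tm - te) / sp$desat_tau))
        seg <- ifelse(t <= tm, ifelse(t >= te, fall, 0),
                      exp(-(t - tm) / sp$desat_tau))
        dip <- dip + sp$desat_depth * seg
      }
    }
  }
  spo2 <- params$resting_spo2 - dip
  if (sp$desat_depth >= params$resting_spo2 - 50) {
    warn("desaturation depth reaches the 50% floor: trajectory clipped")
    spo2 <- pmax(spo2, 50)
  }
  out <- tibble(time_s = t, spo2 = spo2)
  attr(out, "trough_times_s") <- troughs
  out
}

# asymmetric two-Gaussian pulse template on beat phase u in [0, 1):
# a systolic peak with fast rise / slow fall plus a dicrotic bump that rides
# the falling edge as a shoulder (a single local maximum per beat, so
# prominence-based peak detection sees exactly one peak and one trough per
# cardiac cycle at any amplitude). Zero mean, peak-to-peak exactly 2, so a
# cardiac AC amplitude A yields a 2A peak-to-peak excursion.
beat_template <- local({
  raw <- function(u) {
    exp(-((u - 0.28) / ifelse(u < 0.28, 0.09, 0.22))^2 / 2) +
      0.22 * exp(-((u - 0.58) / 0.14)^2 / 2)
  }
  ug <- seq(0, 1, length.out = 4096 + 1)[-(4096 + 1)]
  gv <- raw(ug)
  mu <- mean(gv)
  pp <- max(gv) - min(gv)
  function(u) (raw(u) - mu) * (2 / pp)
})

# red/infrared channel pair for a given saturation trajectory: pulsatile
# template train at the subject's heart rate, red AC scaled so the
# instantaneous ratio of ratios equals (104 - SpO2)/17, respiratory
# amplitude modulation common to both wavelengths, DC-proportional drift,
# additive Gaussian noise. Consumes RNG; call inside withr::with_seed.
synthesize_channels <- function(t, spo2, sp, params) {
  n <- length(t)
  phi0 <- runif(1)
  phi_r <- runif(1, 0, 2 * pi)
  phi_d <- runif(1, 0, 2 * pi)
  g <- beat_template((params$heart_rate / 60 * t + phi0) %% 1)
  a_ir <- sp$ac_amplitude *
    (1 + params$respiration_mod_depth *
       sin(2 * pi * params$respiration_rate * t + phi_r))
  r_t <- (104 - spo2) / 17
  dc_ir <- sp$dc_level
  dc_red <- 0.5 * sp$dc_level
  a_red <- r_t * (dc_red / dc_ir) * a_ir
  drift <- params$drift_amplitude * sin(2 * pi * t / 120 + phi_d)
  list(
    red = dc_red + a_red * g + drift * (dc_red / dc_ir) +
      rnorm(n, 0, params$noise_sd),
    infrared = dc_ir + a_ir * g + drift + rnorm(n, 0, params$noise_sd)
  )
}

#' Synthesise a recording from an arbitrary SpO2 trajectory
#'
#' Generates a single-site [ppg_recording()] whose red/infrared channels
#' encode a caller-supplied saturation trajectory (for example a step or a
#' plateau), using the same signal model as [simulate_subject()]. The button
#' channel is all zero.
#'
#' @param trajectory Data frame with columns `time_s` (uniform grid) and
#'   `spo2` (percent).
#' @param params A [subject_params()] object (site parameters, heart rate,
#'   modulation, noise and seed are taken from it).
#' @param site Which site's [site_params()] to use.
#' @param fs Sampling rate, Hz; inferred from `time_s` if `NULL`.
#' @return A `ppg_recording`.
#' @export
simulate_from_trajectory <- function(trajectory, params = subject_params(),
                                     site = c("ear", "finger"), fs = NULL) {
  site <- match.arg(site)
  stopifnot(inherits(params, "subject_params"))
  if (!all(c("time_s", "spo2") %in% names(trajectory))) {
    abort_format("`trajectory` must have columns time_s and spo2")
  }
  t <- trajectory$time_s
  if (is.null(fs)) fs <- 1 / median(diff(t))
  withr::with_seed(params$seed, {
    ch <- synthesize_channels(t, trajectory$spo2, params[[site]], params)
    ppg_recording(time_s = t, red = ch$red, infrared = ch$infrared,
                  button = rep(0, length(t)), fs = fs,
                  subject_id = params$subject_id, site = site,
                  sex = params$sex, age = params$age)
  })
}

#' Simulate one subject's dual-site PPG recordings
#'
#' Generates red and infrared channels for the ear and finger sites plus the
#' button event channel, following the protocol timeline. The red AC
#' amplitude is scaled so that the instantaneous per-beat ratio of ratios
#' equals `R(t) = (104 - SpO2(t)) / 17`, the inverse of the linear
#' calibration, so the extraction chain should recover the injected
#' saturation trajectory. Respiratory amplitude modulation applies equally
#' to both wavelengths (and hence cancels in the ratio), drift scales with
#' each channel's DC level, and Gaussian noise is added per sample.
#'
#' @param params A [subject_params()] object.
#' @param timeline A [make_protocol()] timeline.
#' @param fs Sampling rate, Hz (>= 25).
#' @param shape Desaturation dip shape, see [build_spo2_trajectory()].
#'
#' @return A list of class `ppg_subject`: `recordings` (named list of
#'   [ppg_recording()] for `ear` and `finger`) and `truth` (list with the
#'   injected `spo2` trajectories, breath-hold `events`, per-site `troughs`
#'   and `delays`, and the `params`). Deterministic given `params$seed`.
#' @export
simulate_subject <- function(params, timeline = make_protocol(), fs = 100,
                             shape = c("gaussian", "exponential")) {
  stopifnot(inherits(params, "subject_params"))
  shape <- match.arg(shape)
  if (fs < 25) abort_config("fs must be >= 25 Hz to preserve pulse morphology")

  total <- protocol_duration(timeline)
  n <- round(total * fs)
  t <- (seq_len(n) - 1) / fs
  holds <- hold_times(timeline)
  button <- rep(0, n)
  for (k in seq_len(nrow(holds))) {
    button[t >= holds$exhale_start_s[k] & t < holds$hold_end_s[k]] <- 1
  }

  traj <- list(
    ear = build_spo2_trajectory(timeline, params, "ear", fs, shape),
    finger = build_spo2_trajectory(timeline, params, "finger", fs, shape)
  )

  recs <- withr::with_seed(params$seed, {
    lapply(c(ear = "ear", finger = "finger"), function(site) {
      ch <- synthesize_channels(t, traj[[site]]$spo2, params[[site]], params)
      ppg_recording(time_s = t, red = ch$red, infrared = ch$infrared,
                    button = button, fs = fs,
                    subject_id = params$subject_id, site = site,
                    sex = params$sex, age = params$age)
    })
  })

  truth <- list(
    spo2 = tibble(time_s = t, ear = traj$ear$spo2, finger = traj$finger$spo2),
    events = tibble(hold = holds$hold,
                    press_time_s = holds$exhale_start_s,
                    release_time_s = holds$hold_end_s),
    troughs = dplyr::bind_rows(
      tibble(hold = holds$hold, site = "ear",
             trough_time_s = attr(traj$ear, "trough_times_s")),
      tibble(hold = holds$hold, site = "finger",
             trough_time_s = attr(traj$finger, "trough_times_s"))
    ),
    delays = tibble(site = c("ear", "finger"),
                    transit_delay_s = c(params$ear$transit_delay,
                                        params$finger$transit_delay)),
    params = params
  )
  structure(list(recordings = recs, truth = truth), class = "ppg_subject")
}

#' @export
print.ppg_subject <- function(x, ...) {
  p <- x$truth$params
  cat(sprintf(
    "<ppg_subject> %s (%s, %g y): HR %g bpm, resting SpO2 %g%%, delays ear %g s / finger %g s\n",
    p$subject_id, p$sex, p$age, p$heart_rate, p$resting_spo2,
    p$ear$transit_delay, p$finger$transit_delay))
  invisible(x)
}

default_param_ranges <- function() {
  list(
    resting_spo2 = c(95.5, 98.5),
    heart_rate = c(55, 85),
    age = c(19, 38),
    ear_delay = c(1, 7.5),
    finger_delay = c(8.5, 28),
    ear_amplitude = c(150, 400),
    amp_ratio = c(2.35, 2.35),
    desat_depth = c(6, 10),
    desat_tau = c(4, 8),
    respiration_rate = c(0.2, 0.3)
  )
}

#' Simulate a dual-site PPG cohort with known ground truth
#'
#' Draws per-subject physiological parameters from uniform ranges (subject
#' `i` uses seed `base_seed + i`, so cohorts are reproducible and prefixes
#' are stable), alternates sexes F/M for a balanced cohort, and simulates
#' each subject with [simulate_subject()]. The default ranges emulate a
#' healthy young cohort: resting SpO2 95.5-98.5%, heart rate 55-85 bpm, ear
#' transit delays U\[1, 7.5\] s and finger delays U\[8.5, 28\] s, and a
#' finger/ear amplitude ratio fixed at 2.35. Parameter draws carry no sex
#' effect, so sex comparisons on simulated cohorts are null by construction.
#'
#' @param n_subjects Number of subjects (>= 1); default 14 (7 F, 7 M).
#' @param base_seed Integer base seed.
#' @param param_ranges Named list overriding entries of the default ranges
#'   (each a `c(min, max)` pair). An empty list keeps the defaults (noted).
#' @param timeline A [make_protocol()] timeline shared by all subjects.
#' @param fs Sampling rate, Hz.
#' @param shape Desaturation dip shape, see [build_spo2_trajectory()].
#'
#' @return A list of class `ppg_cohort`: `recordings` (tibble with
#'   `subject_id`, `site`, and a `recording` list-column), `truth` (one row
#'   per subject with every injected parameter), `events` (true per-subject
#'   hold times), plus `timeline` and `fs`.
#' @export
simulate_cohort <- function(n_subjects = 14, base_seed = 1,
                            param_ranges = list(),
                            timeline = make_protocol(), fs = 100,
                            shape = c("gaussian", "exponential")) {
  if (n_subjects < 1) abort_config("n_subjects must be >= 1")
  shape <- match.arg(shape)
  rng <- default_param_ranges()
  if (length(param_ranges) == 0) {
    inform("simulate_cohort: using default parameter ranges")
  } else {
    extra <- setdiff(names(param_ranges), names(rng))
    if (length(extra)) {
      abort_config(sprintf("unknown param_ranges entries: %s",
                           paste(extra, collapse = ", ")))
    }
    rng <- modifyList(rng, param_ranges)
  }

  subjects <- vector("list", n_subjects)
  truth_rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    seed_i <- as.integer(base_seed + i)
    sex_i <- if (i %% 2 == 1) "F" else "M"
    pars <- withr::with_seed(seed_i, {
      u <- function(nm) runif(1, rng[[nm]][1], rng[[nm]][2])
      ear_amp <- u("ear_amplitude")
      list(
        resting_spo2 = u("resting_spo2"), heart_rate = u("heart_rate"),
        age = round(u("age")), ear_delay = u("ear_delay"),
        finger_delay = u("finger_delay"), ear_amplitude = ear_amp,
        amp_ratio = u("amp_ratio"), desat_depth = u("desat_depth"),
        desat_tau = u("desat_tau"), respiration_rate = u("respiration_rate")
      )
    })
    sp <- subject_params(
      subject_id = sprintf("S%02d", i), sex = sex_i, age = pars$age,
      heart_rate = pars$heart_rate, resting_spo2 = pars$resting_spo2,
      ear = site_params(ac_amplitude = pars$ear_amplitude,
                        transit_delay = pars$ear_delay,
                        desat_depth = pars$desat_depth,
                        desat_tau = pars$desat_tau),
      finger = site_params(ac_amplitude = pars$amp_ratio * pars$ear_amplitude,
                           transit_delay = pars$finger_delay,
                           desat_depth = pars$desat_depth,
                           desat_tau = pars$desat_tau),
      respiration_rate = pars$respiration_rate, seed = seed_i
    )
    subjects[[i]] <- simulate_subject(sp, timeline, fs, shape)
    truth_rows[[i]] <- tibble(
      subject_id = sp$subject_id, sex = sex_i, age = pars$age,
      heart_rate = pars$heart_rate, resting_spo2 = pars$resting_spo2,
      ear_delay = pars$ear_delay, finger_delay = pars$finger_delay,
      ear_amplitude = pars$ear_amplitude,
      finger_amplitude = pars$amp_ratio * pars$ear_amplitude,
      amp_ratio = pars$amp_ratio, desat_depth = pars$desat_depth,
      desat_tau = pars$desat_tau, respiration_rate = pars$respiration_rate,
      seed = seed_i
    )
  }

  recordings <- dplyr::bind_rows(lapply(seq_len(n_subjects), function(i) {
    tibble(
      subject_id = sprintf("S%02d", i),
      site = c("ear", "finger"),
      recording = list(subjects[[i]]$recordings$ear,
                       subjects[[i]]$recordings$finger)
    )
  }))
  events <- dplyr::bind_rows(lapply(seq_len(n_subjects), function(i) {
    dplyr::mutate(subjects[[i]]$truth$events,
                  subject_id = sprintf("S%02d", i), .before = 1)
  }))

  structure(list(
    recordings = recordings,
    truth = dplyr::bind_rows(truth_rows),
    events = events,
    timeline = timeline, fs = fs
  ), class = "ppg_cohort")
}

#' @export
print.ppg_cohort <- function(x, ...) {
  cat(sprintf("<ppg_cohort> %d subjects (%d F / %d M), %g s protocol at %g Hz\n",
              nrow(x$truth), sum(x$truth$sex == "F"), sum(x$truth$sex == "M"),
              protocol_duration(x$timeline), x$fs))
  invisible(x)
}
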