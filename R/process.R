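#' Process one subject's paired recordings
#'
#' Runs the full per-subject analysis: SpO2 extraction at both sites,
#' breath-hold segmentation from the button channel, per-site desaturation
#' delays, resting SpO2 and resting infrared amplitude over the pre-exhale
#' window, and heart rate from the ear pulse peaks.
#'
#' @param ear,finger [ppg_recording()] objects for the two sites.
#' @param config An [spo2_config()].
#' @param trough_window,trough_prominence Passed to [compute_delays()].
#' @param min_hold_s Debounce threshold for [segment_breath_holds()].
#' @param resting_window_s Resting-average window, seconds.
#'
#' @return A list of class `subject_result` with elements `spo2` (list of
#'   the two series), `events`, `delays` (a `delay_result`) and `row`, a
#'   one-row tibble of per-subject statistics ready for [summarize_cohort()].
#' @export
process_subject <- function(ear, finger, config = spo2_config(),
                            trough_window = 45, trough_prominence = 1,
                            min_hold_s = 2, resting_window_s = 60) {
  meta <- recording_meta(ear)
  s_ear <- extract_spo2(ear, config)
  s_finger <- extract_spo2(finger, config)
  events <- segment_breath_holds(ear, min_duration = min_hold_s)
  if (nrow(events) == 0) {
    abort_degenerate(sprintf("subject %s: no breath holds in button channel",
                             meta$subject_id))
  }
  delays <- compute_delays(events, s_ear, s_finger,
                           window = trough_window,
                           min_prominence = trough_prominence)
  first_press <- events$press_time_s[1]
  g <- glance(delays)
  row <- tibble(
    subject_id = meta$subject_id,
    sex = meta$sex,
    age = meta$age,
    resting_spo2_ear = resting_spo2(s_ear, first_press, resting_window_s),
    resting_spo2_finger = resting_spo2(s_finger, first_press, resting_window_s),
    amp_ear = resting_amplitude(s_ear, first_press, resting_window_s),
    amp_finger = resting_amplitude(s_finger, first_press, resting_window_s),
    mean_delay_ear = g$mean_delay_ear_s,
    mean_delay_finger = g$mean_delay_finger_s,
    range_ear = g$range_ear_s,
    range_finger = g$range_finger_s,
    relative_delay = g$relative_delay_s,
    heart_rate = estimate_heart_rate(s_ear)
  )
  structure(list(spo2 = list(ear = s_ear, finger = s_finger),
                 events = events, delays = delays, row = row),
            class = "subject_result")
}

#' Process every subject of a simulated or loaded cohort
#'
#' @param cohort A `ppg_cohort` (see [simulate_cohort()]) or a tibble like
#'   its `recordings` element (`subject_id`, `site`, `recording` list-col).
#' @inheritParams process_subject
#' @return A `cohort_dataset` tibble: one row per subject with the columns
#'   of `process_subject()$row`. The per-subject `subject_result` objects
#'   are kept in the `details` attribute.
#' @export
process_cohort <- function(cohort, config = spo2_config(),
                           trough_window = 45, trough_prominence = 1,
                           min_hold_s = 2, resting_window_s = 60) {
  recs <- if (inherits(cohort, "ppg_cohort")) cohort$recordings else cohort
  ids <- unique(recs$subject_id)
  details <- vector("list", length(ids))
  names(details) <- ids
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sub <- recs[recs$subject_id == ids[i], ]
    ear <- sub$recording[[which(sub$site == "ear")]]
    finger <- sub$recording[[which(sub$site == "finger")]]
    details[[i]] <- process_subject(ear, finger, config,
                                    trough_window, trough_prominence,
                                    min_hold_s, resting_window_s)
    rows[[i]] <- details[[i]]$row
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "details") <- details
  class(out) <- c("cohort_dataset", class(out))
  out
}

#' Cohort-level summary statistics
#'
#' Aggregates a per-subject table into the cohort-level comparison: RMS and
#' mean ear-minus-finger resting SpO2 difference, healthy-range (94-100%)
#' classification agreement, normalised amplitudes with the mean finger/ear
#' ratio, sex-stratified delay means and SDs, Welch t-tests of the delays by
#' sex, and Pearson correlations of age with relative delay and of heart
#' rate with the per-site absolute delays. Statistics whose sample-size
#' requirements are not met are reported as `NA` with a note rather than
#' failing the whole summary.
#'
#' @param data A `cohort_dataset` from [process_cohort()], or any data frame
#'   with the same per-subject columns.
#' @param paired_sex_test Use a paired t-test for the sex comparison instead
#'   of the default unpaired Welch test (requires balanced groups).
#' @return A list of class `cohort_summary`: `per_subject`, `scalars`
#'   (rms_site_diff, mean_site_diff, healthy_agreement, amp_ratio_mean,
#'   n_subjects), `delay_by_sex`, `amplitude` (an `amplitude_summary`),
#'   `tests` and `correlations` tibbles.
#' @export
summarize_cohort <- function(data, paired_sex_test = FALSE) {
  data <- as_tibble(data)
  n <- nrow(data)
  if (n == 0) {
    warn("empty cohort: only header-level structure returned")
    return(structure(list(
      per_subject = data,
      scalars = list(rms_site_diff = NA_real_, mean_site_diff = NA_real_,
                     healthy_agreement = NA_real_, amp_ratio_mean = NA_real_,
                     n_subjects = 0L),
      delay_by_sex = tibble(), amplitude = NULL,
      tests = tibble(), correlations = tibble()
    ), class = "cohort_summary"))
  }
  if (n == 1) {
    warn("single-subject cohort: between-subject statistics undefined (NA)")
  }

  diff_summary <- site_difference_summary(data$resting_spo2_ear,
                                          data$resting_spo2_finger)
  agreement <- healthy_range_agreement(data$resting_spo2_ear,
                                       data$resting_spo2_finger)
  amp <- amplitude_summary(data)

  sex_stats <- function(d) {
    tibble(
      n = nrow(d),
      relative_mean = mean(d$relative_delay),
      relative_sd = if (nrow(d) > 1) sd(d$relative_delay) else NA_real_,
      finger_mean = mean(d$mean_delay_finger),
      finger_sd = if (nrow(d) > 1) sd(d$mean_delay_finger) else NA_real_,
      ear_mean = mean(d$mean_delay_ear),
      ear_sd = if (nrow(d) > 1) sd(d$mean_delay_ear) else NA_real_
    )
  }
  by_sex <- dplyr::bind_rows(
    if (any(data$sex == "F", na.rm = TRUE))
      dplyr::mutate(sex_stats(data[which(data$sex == "F"), ]), group = "Female", .before = 1),
    if (any(data$sex == "M", na.rm = TRUE))
      dplyr::mutate(sex_stats(data[which(data$sex == "M"), ]), group = "Male", .before = 1),
    dplyr::mutate(sex_stats(data), group = "Total", .before = 1)
  )

  f <- data[which(data$sex == "F"), ]
  m <- data[which(data$sex == "M"), ]
  safe_test <- function(label, a, b) {
    res <- tryCatch(group_ttest(a, b, paired = paired_sex_test),
                    error = function(e) {
                      inform(sprintf("skipping %s: %s", label, conditionMessage(e)))
                      tibble(statistic = NA_real_, df = NA_real_,
                             p_value = NA_real_, mean_a = NA_real_,
                             mean_b = NA_real_, method = NA_character_)
                    })
    dplyr::mutate(res, test = label, .before = 1)
  }
  tests <- dplyr::bind_rows(
    safe_test("relative_delay_by_sex", f$relative_delay, m$relative_delay),
    safe_test("finger_delay_by_sex", f$mean_delay_finger, m$mean_delay_finger),
    safe_test("ear_delay_by_sex", f$mean_delay_ear, m$mean_delay_ear),
    safe_test("finger_amplitude_by_sex", f$amp_finger, m$amp_finger),
    safe_test("ear_amplitude_by_sex", f$amp_ear, m$amp_ear)
  )

  safe_cor <- function(label, x, y) {
    res <- tryCatch(pearson(x, y),
                    error = function(e) {
                      inform(sprintf("skipping %s: %s", label, conditionMessage(e)))
                      tibble(r = NA_real_, p_value = NA_real_, n = NA_integer_)
                    })
    dplyr::mutate(res, pair = label, .before = 1)
  }
  correlations <- dplyr::bind_rows(
    safe_cor("age_vs_relative_delay", data$age, data$relative_delay),
    safe_cor("heart_rate_vs_ear_delay", data$heart_rate, data$mean_delay_ear),
    safe_cor("heart_rate_vs_finger_delay", data$heart_rate, data$mean_delay_finger)
  )

  structure(list(
    per_subject = dplyr::select(amp$per_subject, dplyr::everything()),
    scalars = list(
      rms_site_diff = diff_summary$rms_diff,
      mean_site_diff = diff_summary$mean_diff,
      healthy_agreement = agreement,
      amp_ratio_mean = amp$amp_ratio_mean,
      n_subjects = n
    ),
    delay_by_sex = by_sex,
    amplitude = amp,
    tests = tests,
    correlations = correlations
  ), class = "cohort_summary")
}

#' @rdname summarize_cohort
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @export
tidy.cohort_summary <- function(x, ...) x$per_subject

#' @rdname summarize_cohort
#' @export
glance.cohort_summary <- function(x, ...) {
  s <- x$scalars
  rel <- x$tests[x$tests$test == "relative_delay_by_sex", , drop = FALSE]
  tot <- x$delay_by_sex[x$delay_by_sex$group == "Total", , drop = FALSE]
  tibble(
    n_subjects = s$n_subjects,
    rms_site_diff = s$rms_site_diff,
    mean_site_diff = s$mean_site_diff,
    healthy_agreement = s$healthy_agreement,
    amp_ratio_mean = s$amp_ratio_mean,
    mean_delay_ear = if (nrow(tot)) tot$ear_mean else NA_real_,
    mean_delay_finger = if (nrow(tot)) tot$finger_mean else NA_real_,
    mean_relative_delay = if (nrow(tot)) tot$relative_mean else NA_real_,
    sex_test_p = if (nrow(rel)) rel$p_value else NA_real_
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  s <- x$scalars
  cat(sprintf("<cohort_summary> %d subjects\n", s$n_subjects))
  cat(sprintf("  Resting SpO2 (ear - finger): RMS %.2f%%, mean %+.2f%%; healthy-range agreement %.0f%%\n",
              s$rms_site_diff, s$mean_site_diff, 100 * s$healthy_agreement))
  cat(sprintf("  Resting amplitude: mean finger/ear ratio %.2f\n", s$amp_ratio_mean))
  if (nrow(x$delay_by_sex)) {
    cat("  SpO2 delay, mean +/- sd (s):\n")
    cat(sprintf("  %-8s %-15s %-15s %-15s\n", "", "Relative", "Finger", "Ear canal"))
    for (i in seq_len(nrow(x$delay_by_sex))) {
      r <- x$delay_by_sex[i, ]
      fmt <- function(m, sdv) {
        if (is.na(sdv)) sprintf("%.2f", m) else sprintf("%.2f +/- %.2f", m, sdv)
      }
      cat(sprintf("  %-8s %-15s %-15s %-15s\n", r$group,
                  fmt(r$relative_mean, r$relative_sd),
                  fmt(r$finger_mean, r$finger_sd),
                  fmt(r$ear_mean, r$ear_sd)))
    }
  }
  invisible(x)
}
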