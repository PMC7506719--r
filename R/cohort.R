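#' Resting SpO2 over the pre-exhale window
#'
#' Mean of the (unsmoothed) SpO2 trace over the normal-breathing window that
#' ends at the first button press, by default the final 60 s before the
#' first exhale.
#'
#' @param spo2 An `spo2_series`.
#' @param first_press Time of the first button press, seconds.
#' @param window Averaging window length, seconds (default 60).
#' @return Mean resting SpO2, percent.
#' @export
resting_spo2 <- function(spo2, first_press, window = 60) {
  stopifnot(inherits(spo2, "spo2_series"))
  if (first_press < window) {
    abort_config(sprintf(
      "resting window needs %g s before the first press; only %g s available",
      window, first_press))
  }
  sel <- spo2$time_s >= first_press - window & spo2$time_s <= first_press
  mean(spo2$spo2[sel], na.rm = TRUE)
}

#' Resting infrared AC amplitude over the pre-exhale window
#'
#' Mean of the infrared AC amplitude envelope (`ac_ir`) over the resting
#' window before the first exhale; the per-site statistic behind the
#' finger/ear amplitude comparison.
#'
#' @inheritParams resting_spo2
#' @return Mean AC amplitude, ADC counts.
#' @export
resting_amplitude <- function(spo2, first_press, window = 60) {
  stopifnot(inherits(spo2, "spo2_series"))
  if (!"ac_ir" %in% names(spo2)) {
    abort_format("series carries no infrared AC envelope (ac_ir)")
  }
  if (first_press < window) {
    abort_config(sprintf(
      "resting window needs %g s before the first press; only %g s available",
      window, first_press))
  }
  sel <- spo2$time_s >= first_press - window & spo2$time_s <= first_press
  mean(spo2$ac_ir[sel], na.rm = TRUE)
}

#' Between-site agreement of resting SpO2
#'
#' Root-mean-square and mean of the per-subject ear-minus-finger resting
#' SpO2 differences (positive mean = higher saturation in the ear).
#'
#' @param ear,finger Equal-length vectors of per-subject resting SpO2 means.
#' @return One-row tibble with `rms_diff`, `mean_diff`, `n`.
#' @export
site_difference_summary <- function(ear, finger) {
  if (length(ear) != length(finger)) {
    abort_format("`ear` and `finger` must have the same length")
  }
  if (length(ear) < 1) abort_format("need at least one paired value")
  d <- ear - finger
  tibble(rms_diff = sqrt(mean(d^2)), mean_diff = mean(d), n = length(d))
}

#' Agreement on healthy-range classification
#'
#' Fraction of subjects for which the two sites agree on whether resting
#' SpO2 lies in the healthy range (closed interval, default 94-100%). Both
#' sites out of range counts as agreement.
#'
#' @inheritParams site_difference_summary
#' @param lo,hi Healthy-range bounds, percent.
#' @return Fraction in \[0, 1\].
#' @export
healthy_range_agreement <- function(ear, finger, lo = 94, hi = 100) {
  if (length(ear) != length(finger)) {
    abort_format("`ear` and `finger` must have the same length")
  }
  in_e <- ear >= lo & ear <= hi
  in_f <- finger >= lo & finger <= hi
  mean(in_e == in_f)
}

#' Normalised resting PPG amplitudes and finger/ear ratio
#'
#' Normalises per-subject resting infrared AC amplitudes to the cohort
#' maximum (so the largest value is exactly 1), computes each subject's
#' finger/ear amplitude ratio and its cohort mean, and, when a `sex` column
#' is present, per-sex means and standard deviations of the raw amplitudes.
#'
#' @param data Data frame with columns `subject_id`, `amp_ear`,
#'   `amp_finger`, and optionally `sex`.
#' @return A list of class `amplitude_summary` with `per_subject`
#'   (normalised amplitudes and ratios), `amp_ratio_mean` and `by_sex`
#'   (possibly empty tibble).
#' @export
amplitude_summary <- function(data) {
  need <- c("subject_id", "amp_ear", "amp_finger")
  if (!all(need %in% names(data))) {
    abort_format(sprintf("`data` must have columns: %s",
                         paste(need, collapse = ", ")))
  }
  ok <- is.finite(data$amp_ear) & is.finite(data$amp_finger) &
    data$amp_ear > 0 & data$amp_finger > 0
  if (any(!ok)) {
    warn(sprintf("amplitude_summary: excluding %d subject(s) with degenerate amplitudes",
                 sum(!ok)))
    data <- data[ok, , drop = FALSE]
  }
  if (nrow(data) == 0) abort_degenerate("no subjects with usable amplitudes")
  amp_max <- max(c(data$amp_ear, data$amp_finger))
  per_subject <- dplyr::mutate(
    as_tibble(data),
    norm_amp_ear = .data$amp_ear / amp_max,
    norm_amp_finger = .data$amp_finger / amp_max,
    amp_ratio = .data$amp_finger / .data$amp_ear
  )
  by_sex <- if ("sex" %in% names(data)) {
    per_subject |>
      dplyr::group_by(.data$sex) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean_amp_finger = mean(.data$amp_finger),
        sd_amp_finger = sd(.data$amp_finger),
        mean_amp_ear = mean(.data$amp_ear),
        sd_amp_ear = sd(.data$amp_ear),
        .groups = "drop"
      )
  } else {
    tibble()
  }
  structure(list(per_subject = per_subject,
                 amp_ratio_mean = mean(per_subject$amp_ratio),
                 by_sex = by_sex),
            class = "amplitude_summary")
}

#' Two-sample t-test between groups
#'
#' Two-sided t-test comparing two groups of per-subject statistics (for
#' example male vs female delays). The default is the unpaired Welch test,
#' appropriate for independent groups; `paired = TRUE` is available for
#' genuinely paired designs.
#'
#' @param a,b Numeric vectors (equal length when `paired`).
#' @param paired Paired test?
#' @return One-row tibble with `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `method`.
#' @export
group_ttest <- function(a, b, paired = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    abort_config("each group needs at least 2 values")
  }
  if (paired) {
    if (length(a) != length(b)) {
      abort_config("paired test needs equal-length groups")
    }
    if (sd(a - b) == 0) {
      abort_degenerate("paired differences have zero variance: t undefined")
    }
  }
  res <- tryCatch(
    t.test(a, b, paired = paired, var.equal = FALSE),
    error = function(e) abort_degenerate(paste("t-test failed:", conditionMessage(e)))
  )
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = res$p.value, mean_a = mean(a), mean_b = mean(b),
         method = if (paired) "paired t" else "Welch t")
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors, length >= 3, each with nonzero variance.
#' @return One-row tibble with `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort_config("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort_degenerate("zero variance: correlation undefined")
  }
  res <- cor.test(x, y, method = "pearson")
  tibble(r = unname(res$estimate), p_value = res$p.value, n = length(x))
}

#' Empirical type-I error of the sex comparison under a null simulation
#'
#' Draws many replicate cohorts in which both sexes share the same delay
#' distribution (no effect), applies [group_ttest()] to each, and reports
#' the fraction of replicates with `p < alpha`. A calibrated test should be
#' close to `alpha`.
#'
#' @param n_reps Number of replicate cohorts (>= 200 recommended).
#' @param n_per_group Subjects per sex (default 7).
#' @param mean,sd Normal delay distribution shared by both groups, seconds.
#' @param alpha Nominal level.
#' @param seed Optional seed for reproducibility.
#' @return Empirical rejection rate (fraction in \[0, 1\]).
#' @export
ttest_type1_error <- function(n_reps = 200, n_per_group = 7,
                              mean = 16.75, sd = 5.88, alpha = 0.05,
                              seed = NULL) {
  run <- function() {
    p <- vapply(seq_len(n_reps), function(i) {
      group_ttest(rnorm(n_per_group, mean, sd),
                  rnorm(n_per_group, mean, sd))$p_value
    }, numeric(1))
    base::mean(p < alpha)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
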