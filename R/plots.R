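#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a PPG recording
#'
#' Raw red and infrared channels (and green if present) against time, with
#' breath-hold periods (button high) shaded.
#'
#' @param object A [ppg_recording()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppg_recording <- function(object, ...) {
  long <- as_tibble(object) |>
    dplyr::select(dplyr::any_of(c("time_s", "green", "red", "infrared"))) |>
    tidyr::pivot_longer(-"time_s", names_to = "channel", values_to = "adc") |>
    dplyr::filter(!is.na(.data$adc))
  holds <- segment_breath_holds(object)
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$adc,
                                          colour = .data$channel))
  if (nrow(holds)) {
    p <- p + ggplot2::geom_rect(
      data = holds, inherit.aes = FALSE, alpha = 0.15,
      ggplot2::aes(xmin = .data$press_time_s, xmax = .data$release_time_s,
                   ymin = -Inf, ymax = Inf))
  }
  m <- recording_meta(object)
  p + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(green = "#2e7d32", red = "#c62828",
                                            infrared = "#4527a0"),
                                 guide = "none") +
    ggplot2::labs(x = "Time (s)", y = "ADC counts",
                  title = sprintf("PPG recording: %s / %s",
                                  m$subject_id %||% "", m$site %||% ""))
}

#' Plot an SpO2 series
#'
#' Raw and smoothed SpO2 traces with breath-hold windows shaded when an
#' event table is supplied.
#'
#' @param object An `spo2_series`.
#' @param events Optional [segment_breath_holds()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spo2_series <- function(object, events = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$spo2))
  if (!is.null(events) && nrow(events)) {
    p <- p + ggplot2::geom_rect(
      data = events, inherit.aes = FALSE, alpha = 0.15,
      ggplot2::aes(xmin = .data$press_time_s, xmax = .data$release_time_s,
                   ymin = -Inf, ymax = Inf))
  }
  p + ggplot2::geom_line(colour = "grey60", linewidth = 0.3, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$spo2_smooth),
                       colour = "#c62828", linewidth = 0.6, na.rm = TRUE) +
    ggplot2::labs(x = "Time (s)", y = expression(SpO[2] ~ "(%)"))
}

#' Per-subject resting SpO2 agreement plot
#'
#' Dot plot of resting SpO2 at both sites for every subject, with the
#' healthy range (94-100%) marked.
#'
#' @param data A `cohort_dataset` (or compatible data frame).
#' @param lo,hi Healthy-range bounds, percent.
#' @return A ggplot object.
#' @export
plot_resting_agreement <- function(data, lo = 94, hi = 100) {
  long <- tidyr::pivot_longer(
    as_tibble(data)[, c("subject_id", "resting_spo2_ear", "resting_spo2_finger")],
    -"subject_id", names_to = "site", values_to = "spo2",
    names_prefix = "resting_spo2_")
  ggplot2::ggplot(long, ggplot2::aes(.data$subject_id, .data$spo2,
                                     colour = .data$site, shape = .data$site)) +
    ggplot2::geom_hline(yintercept = c(lo, hi), linetype = "dotted",
                        colour = "#2e7d32") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "Subject", y = expression("Resting" ~ SpO[2] ~ "(%)"),
                  colour = "Site", shape = "Site")
}

#' Per-subject desaturation delay plot
#'
#' Ear, finger and relative delays for every subject, with the per-subject
#' range of the per-hold values as error bars where available.
#'
#' @param data A `cohort_dataset` (or compatible data frame).
#' @return A ggplot object.
#' @export
plot_delay_summary <- function(data) {
  d <- as_tibble(data)
  long <- dplyr::bind_rows(
    tibble(subject_id = d$subject_id, what = "ear",
           delay = d$mean_delay_ear, range = d$range_ear),
    tibble(subject_id = d$subject_id, what = "finger",
           delay = d$mean_delay_finger, range = d$range_finger),
    tibble(subject_id = d$subject_id, what = "relative",
           delay = d$relative_delay, range = NA_real_)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$subject_id, .data$delay,
                                     fill = .data$what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$delay - .data$range / 2,
                   ymax = .data$delay + .data$range / 2),
      position = "dodge", na.rm = TRUE, linewidth = 0.3) +
    ggplot2::labs(x = "Subject", y = "Delay (s)", fill = NULL)
}

#' Normalised resting amplitude plot
#'
#' Normalised resting infrared AC amplitudes per subject and site.
#'
#' @param amp An `amplitude_summary` (see [amplitude_summary()]) or a
#'   `cohort_summary`.
#' @return A ggplot object.
#' @export
plot_amplitudes <- function(amp) {
  if (inherits(amp, "cohort_summary")) amp <- amp$amplitude
  stopifnot(inherits(amp, "amplitude_summary"))
  long <- tidyr::pivot_longer(
    amp$per_subject[, c("subject_id", "norm_amp_ear", "norm_amp_finger")],
    -"subject_id", names_to = "site", values_to = "amplitude",
    names_prefix = "norm_amp_")
  ggplot2::ggplot(long, ggplot2::aes(.data$subject_id, .data$amplitude,
                                     colour = .data$site, shape = .data$site)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "Subject", y = "Normalised resting AC amplitude",
                  colour = "Site", shape = "Site")
}
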