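#' SpO2 extraction configuration
#'
#' Collects the tunable parameters of the SpO2 extraction chain. Prominence
#' thresholds are in raw ADC units and therefore sensor-scale dependent; the
#' defaults (150 infrared / 30 red) match a sensor whose infrared AC
#' amplitude is roughly five times the red AC amplitude.
#'
#' @param bandpass_low_hz,bandpass_high_hz AC band edges, Hz.
#' @param dc_cutoff_hz DC low-pass corner, Hz.
#' @param prominence_ir,prominence_red Minimum peak prominences, ADC counts.
#' @param smooth_window_s Centred moving-average window for the smoothed
#'   SpO2 trace used in event detection, seconds.
#' @param clip If `TRUE`, clip calibrated SpO2 into \[0, 100\]%.
#' @param max_gap_s Invalid-ratio gaps shorter than this are linearly
#'   interpolated in the SpO2 trace; longer gaps stay missing.
#'
#' @return A list of class `spo2_config`.
#' @export
spo2_config <- function(bandpass_low_hz = 1, bandpass_high_hz = 30,
                        dc_cutoff_hz = 0.01, prominence_ir = 150,
                        prominence_red = 30, smooth_window_s = 3,
                        clip = FALSE, max_gap_s = 2) {
  cfg <- list(
    bandpass_low_hz = bandpass_low_hz, bandpass_high_hz = bandpass_high_hz,
    dc_cutoff_hz = dc_cutoff_hz, prominence_ir = prominence_ir,
    prominence_red = prominence_red, smooth_window_s = smooth_window_s,
    clip = isTRUE(clip), max_gap_s = max_gap_s
  )
  num <- cfg[setdiff(names(cfg), "clip")]
  if (any(!vapply(num, function(v) is.numeric(v) && length(v) == 1 &&
                    is.finite(v) && v >= 0, logical(1)))) {
    abort_config("all spo2_config values must be single non-negative numbers")
  }
  structure(cfg, class = "spo2_config")
}

#' @rdname spo2_config
#' @param path Path to a YAML file whose keys override the defaults.
#' @export
read_spo2_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(spo2_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    abort_config(sprintf("unknown config keys: %s", paste(extra, collapse = ", ")))
  }
  do.call(spo2_config, vals)
}

#' Ratio of ratios from AC and DC traces
#'
#' Computes the dimensionless ratio of ratios
#' `R = (AC_red / DC_red) / (AC_ir / DC_ir)` pointwise. Samples where a
#' denominator is non-positive or non-finite are masked (`NA`) and their
#' count reported.
#'
#' @param ac_red,dc_red,ac_ir,dc_ir Numeric vectors of equal length.
#' @return Numeric vector of R values (NA where masked).
#' @export
ratio_of_ratios <- function(ac_red, dc_red, ac_ir, dc_ir) {
  n <- length(ac_red)
  if (any(c(length(dc_red), length(ac_ir), length(dc_ir)) != n)) {
    abort_format("all four traces must have the same length")
  }
  bad <- !(is.finite(ac_red) & is.finite(dc_red) & is.finite(ac_ir) &
             is.finite(dc_ir) & dc_red > 0 & dc_ir > 0 & ac_ir > 0)
  r <- (ac_red / dc_red) / (ac_ir / dc_ir)
  if (any(bad)) {
    r[bad] <- NA_real_
    inform(sprintf("ratio_of_ratios: masked %d invalid sample(s)", sum(bad)))
  }
  r
}

#' Linear SpO2 calibration
#'
#' Maps the ratio of ratios to percent saturation with the empirical linear
#' calibration `SpO2 = 104 - 17 R`. Values above 100% are possible for small
#' R and are reported as-is unless `clip = TRUE`.
#'
#' @param r Numeric vector of ratio-of-ratios values.
#' @param clip Clip the result into \[0, 100\]?
#' @return Numeric vector of SpO2 values in percent.
#' @export
calibrate_spo2 <- function(r, clip = FALSE) {
  s <- 104 - 17 * r
  if (isTRUE(clip)) s <- pmin(pmax(s, 0), 100)
  s
}

#' Extract a calibrated SpO2 series from a PPG recording
#'
#' Runs the full chain on the red and infrared channels: band-pass AC
#' isolation, prominence-based peak/trough detection, envelope interpolation
#' (AC amplitude = |peak envelope| + |trough envelope|), 0.01 Hz DC baseline,
#' ratio of ratios and linear calibration. A smoothed copy of the SpO2 trace
#' (centred moving average, default 3 s) is stored alongside the raw trace
#' and is what event detection uses; masked samples are linearly interpolated
#' when the gap is short.
#'
#' @param rec A [ppg_recording()].
#' @param config An [spo2_config()].
#'
#' @return An `spo2_series` tibble with columns `time_s`, `spo2`,
#'   `spo2_smooth`, `r`, `ac_red`, `ac_ir`, `dc_red`, `dc_ir`. Attributes:
#'   `fs`, `meta`, `config`, `ir_peak_times` (seconds, for heart-rate
#'   estimation).
#' @seealso [estimate_heart_rate()], [compute_delays()]
#' @export
extract_spo2 <- function(rec, config = spo2_config()) {
  validate_ppg_recording(rec)
  stopifnot(inherits(config, "spo2_config"))
  fs <- recording_fs(rec)
  t <- rec$time_s

  chain <- function(raw, prominence, channel) {
    ac <- bandpass_ac(raw, fs, config$bandpass_low_hz, config$bandpass_high_hz)
    ext <- detect_extrema(ac, fs, prominence, t0 = t[1])
    env <- ac_envelope(ext, t, channel = channel)
    list(env = env, ext = ext)
  }
  red <- chain(rec$red, config$prominence_red, "red")
  ir <- chain(rec$infrared, config$prominence_ir, "infrared")
  dc_red <- lowpass_dc(rec$red, fs, config$dc_cutoff_hz)
  dc_ir <- lowpass_dc(rec$infrared, fs, config$dc_cutoff_hz)

  r <- ratio_of_ratios(red$env$ac_amplitude, dc_red, ir$env$ac_amplitude, dc_ir)
  spo2 <- calibrate_spo2(r, clip = config$clip)
  spo2 <- fill_short_gaps(t, spo2, config$max_gap_s)
  k <- max(1L, as.integer(round(config$smooth_window_s * fs)))
  if (k %% 2L == 0L) k <- k + 1L

  out <- tibble(
    time_s = t, spo2 = spo2, spo2_smooth = moving_average(spo2, k),
    r = r, ac_red = red$env$ac_amplitude, ac_ir = ir$env$ac_amplitude,
    dc_red = dc_red, dc_ir = dc_ir
  )
  attr(out, "fs") <- fs
  attr(out, "meta") <- recording_meta(rec)
  attr(out, "config") <- config
  attr(out, "ir_peak_times") <- ir$ext$peaks$time_s
  class(out) <- c("spo2_series", class(out))
  out
}

#' Assemble an SpO2 series from an existing trace
#'
#' Wraps a plain `time_s`/`spo2` table (for example a simulated ground-truth
#' trajectory) as an `spo2_series` so that event detection and delay
#' estimation can run on it directly.
#'
#' @param df Data frame with columns `time_s` and `spo2` on a uniform grid.
#' @param fs Sampling rate in Hz; inferred from `time_s` if omitted.
#' @param config An [spo2_config()] (only the smoothing window is used).
#' @return An `spo2_series` tibble.
#' @export
as_spo2_series <- function(df, fs = NULL, config = spo2_config()) {
  if (!all(c("time_s", "spo2") %in% names(df))) {
    abort_format("`df` must have columns time_s and spo2")
  }
  if (is.null(fs)) fs <- 1 / median(diff(df$time_s))
  k <- max(1L, as.integer(round(config$smooth_window_s * fs)))
  if (k %% 2L == 0L) k <- k + 1L
  out <- tibble(time_s = df$time_s, spo2 = df$spo2,
                spo2_smooth = moving_average(df$spo2, k))
  attr(out, "fs") <- fs
  attr(out, "config") <- config
  class(out) <- c("spo2_series", class(out))
  out
}

# linearly interpolate NA runs shorter than max_gap_s; longer runs stay NA
fill_short_gaps <- function(t, y, max_gap_s) {
  na <- is.na(y)
  if (!any(na) || all(na)) return(y)
  runs <- rle(na)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  filled <- approx(t[!na], y[!na], xout = t, rule = 2)$y
  out <- y
  for (i in which(runs$values)) {
    if (t[ends[i]] - t[starts[i]] < max_gap_s) {
      idx <- starts[i]:ends[i]
      out[idx] <- filled[idx]
    }
  }
  out
}

#' Heart rate from detected pulse peaks
#'
#' Median inter-peak interval of the infrared AC pulse peaks, converted to
#' beats per minute. The median makes the estimate robust to isolated missed
#' or spurious beats.
#'
#' @param peak_times Peak times in seconds (e.g. the `ir_peak_times`
#'   attribute of an `spo2_series`), or an `spo2_series` itself.
#' @return Heart rate in beats/min.
#' @export
estimate_heart_rate <- function(peak_times) {
  if (inherits(peak_times, "spo2_series")) {
    peak_times <- attr(peak_times, "ir_peak_times")
  }
  if (length(peak_times) < 2) {
    abort_degenerate("heart rate undefined: fewer than 2 pulse peaks")
  }
  60 / median(diff(sort(peak_times)))
}

#' @export
print.spo2_series <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("<spo2_series> %s%s%.1f s at %g Hz, mean SpO2 %.1f%%\n",
              if (!is.null(m)) paste0(m$subject_id, "/", m$site, ", ") else "",
              "", nrow(x) / attr(x, "fs"), attr(x, "fs"),
              mean(x$spo2, na.rm = TRUE)))
  NextMethod()
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @rdname extract_spo2
#' @param x An `spo2_series`.
#' @param ... Unused.
#' @export
glance.spo2_series <- function(x, ...) {
  hr <- tryCatch(estimate_heart_rate(x), error = function(e) NA_real_)
  tibble(
    n = nrow(x),
    duration_s = nrow(x) / attr(x, "fs"),
    mean_spo2 = mean(x$spo2, na.rm = TRUE),
    min_spo2 = min(x$spo2, na.rm = TRUE),
    heart_rate_bpm = hr
  )
}
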