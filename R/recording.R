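#' Construct a dual-wavelength PPG recording
#'
#' A `ppg_recording` is a tibble with one row per sample and columns
#' `time_s`, `green`, `red`, `infrared` (ADC counts; `green` may be all-`NA`)
#' and `button` (0/1 event channel, held high from exhale start to breath-hold
#' end), carrying the sampling rate and per-recording metadata (subject id,
#' anatomical site, sex, age) as attributes.
#'
#' @param time_s Uniform time grid in seconds, 0-based at record start.
#' @param red,infrared Raw channel samples (ADC counts).
#' @param button Binary event channel (0/1).
#' @param green Optional green-channel samples; `NA` if absent.
#' @param fs Sampling rate, Hz.
#' @param subject_id,site,sex,age Recording metadata; `site` is `"ear"` or
#'   `"finger"`.
#'
#' @return A validated `ppg_recording` tibble.
#' @export
ppg_recording <- function(time_s, red, infrared, button, green = NULL,
                          fs, subject_id = "S01", site = c("ear", "finger"),
                          sex = NA_character_, age = NA_real_) {
  site <- match.arg(site)
  fs <- as.numeric(fs)
  age <- as.numeric(age)
  sex <- as.character(sex)
  n <- length(time_s)
  if (is.null(green)) green <- rep(NA_real_, n)
  out <- tibble(
    time_s = as.numeric(time_s),
    green = as.numeric(green),
    red = as.numeric(red),
    infrared = as.numeric(infrared),
    button = as.numeric(button)
  )
  attr(out, "fs") <- fs
  attr(out, "meta") <- list(subject_id = subject_id, site = site,
                            sex = sex, age = age)
  class(out) <- c("ppg_recording", class(out))
  validate_ppg_recording(out)
}

#' @rdname ppg_recording
#' @param rec A `ppg_recording`.
#' @export
validate_ppg_recording <- function(rec) {
  need <- c("time_s", "red", "infrared", "button")
  for (col in need) {
    if (!col %in% names(rec)) {
      abort_format(sprintf("missing channel: %s", col))
    }
  }
  fs <- attr(rec, "fs")
  if (is.null(fs) || !is.finite(fs) || fs <= 0) {
    abort_format("fs: must be a positive number")
  }
  b <- rec$button
  if (any(!b %in% c(0, 1))) {
    abort_format("button: values outside {0, 1}")
  }
  if (nrow(rec) > 1) {
    d <- diff(rec$time_s)
    if (any(d <= 0)) abort_format("time_s: grid not strictly increasing")
    if (max(abs(d - 1 / fs)) > 1e-6 / fs + 1e-9) {
      abort_format(sprintf(
        "time_s: grid spacing inconsistent with fs = %g Hz", fs))
    }
  }
  rec
}

#' @rdname ppg_recording
#' @export
recording_fs <- function(rec) attr(rec, "fs")

#' @rdname ppg_recording
#' @export
recording_meta <- function(rec) attr(rec, "meta")

#' @export
print.ppg_recording <- function(x, ...) {
  m <- recording_meta(x)
  cat(sprintf("<ppg_recording> subject %s, site %s, %g Hz, %.1f s (%d samples)\n",
              m$subject_id %||% "?", m$site %||% "?", recording_fs(x),
              nrow(x) / recording_fs(x), nrow(x)))
  NextMethod()
}
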