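#' Segment breath holds from the button event channel
#'
#' The subject holds the button down from the start of the exhale until the
#' end of the breath hold, so each high segment of the binary button channel
#' delimits one exhale+hold manoeuvre. Isolated single-sample glitches are
#' removed, segments shorter than a debounce threshold are discarded, and a
#' high segment still open at the record end is dropped with a warning.
#'
#' @param rec A [ppg_recording()], or a numeric 0/1 vector.
#' @param fs Sampling rate in Hz (taken from `rec` when it is a recording).
#' @param min_duration Minimum accepted segment duration, seconds
#'   (default 2, debounce).
#'
#' @return A tibble with columns `hold` (1-based index), `press_time_s`
#'   (first high sample) and `release_time_s` (first low sample after the
#'   segment, i.e. the hold end).
#' @export
segment_breath_holds <- function(rec, fs = NULL, min_duration = 2) {
  if (inherits(rec, "ppg_recording")) {
    fs <- recording_fs(rec)
    t <- rec$time_s
    b <- rec$button
  } else {
    if (is.null(fs)) abort_config("`fs` required when `rec` is a plain vector")
    b <- rec
    t <- (seq_along(b) - 1) / fs
  }
  if (any(!b %in% c(0, 1))) abort_format("button: values outside {0, 1}")
  b <- despike_binary(b)

  runs <- rle(b)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hi <- which(runs$values == 1)
  if (length(hi) == 0) {
    return(tibble(hold = integer(0), press_time_s = numeric(0),
                  release_time_s = numeric(0)))
  }
  open_at_end <- ends[hi] == length(b)
  if (any(open_at_end)) {
    warn("button still pressed at record end: unmatched segment dropped")
    hi <- hi[!open_at_end]
  }
  press <- t[starts[hi]]
  release <- t[pmin(ends[hi] + 1L, length(t))]
  keep <- (release - press) >= min_duration
  tibble(hold = seq_len(sum(keep)),
         press_time_s = press[keep], release_time_s = release[keep])
}

# flip isolated single-sample runs to their neighbours' value
despike_binary <- function(b) {
  repeat {
    runs <- rle(b)
    k <- length(runs$lengths)
    if (k < 3) return(b)
    spike <- which(runs$lengths == 1L)
    spike <- spike[spike > 1L & spike < k]
    if (length(spike) == 0) return(b)
    runs$values[spike] <- runs$values[spike - 1L]
    b <- inverse.rle(runs)
  }
}

#' Locate the first SpO2 trough after a breath-hold release
#'
#' Searches the smoothed SpO2 trace in a bounded window after the button
#' release (the moment of true minimal blood oxygen at the lungs) and
#' returns the earliest local minimum whose prominence, measured within the
#' window, reaches a threshold. Ties between equal-depth minima go to the
#' earliest. The search segment starts 15 s before the release so that a dip
#' centred at (or just after) the release still has enough left-side context
#' for its prominence to register; candidate troughs earlier than 1 s before
#' the release are ignored.
#'
#' @param spo2 An `spo2_series` (see [extract_spo2()], [as_spo2_series()]).
#' @param release_time Button release time, seconds.
#' @param window Search window length after the release, seconds.
#' @param min_prominence Minimum trough prominence, percent SpO2.
#'
#' @return The trough time in seconds, or `NA_real_` when no qualifying
#'   trough exists.
#' @export
find_spo2_trough <- function(spo2, release_time, window = 45,
                             min_prominence = 1) {
  stopifnot(inherits(spo2, "spo2_series"))
  if (window <= 0) abort_config("`window` must be > 0")
  t <- spo2$time_s
  if (release_time < t[1] || release_time > t[length(t)]) {
    abort_config("release_time outside the record")
  }
  fs <- attr(spo2, "fs")
  idx <- which(t >= release_time - 15 & t <= release_time + window)
  y <- spo2$spo2_smooth[idx]
  if (anyNA(y)) {
    ok <- !is.na(y)
    if (sum(ok) < 3) return(NA_real_)
    y <- approx(t[idx][ok], y[ok], xout = t[idx], rule = 2)$y
  }
  ext <- detect_extrema(-y, fs, min_prominence, t0 = t[idx[1]])
  cand <- ext$peaks[ext$peaks$time_s >= release_time - 1, , drop = FALSE]
  if (nrow(cand) == 0) return(NA_real_)
  min(cand$time_s)
}

#' Per-subject breath-hold desaturation delays for ear and finger
#'
#' For every breath hold and site, the absolute delay is the time from the
#' button release to the first qualifying SpO2 trough. Per-site means and
#' ranges (max - min over holds) summarise the subject; the relative delay
#' is `mean(finger) - mean(ear)`, positive when the ear leads.
#'
#' @param events Breath-hold table from [segment_breath_holds()].
#' @param spo2_ear,spo2_finger `spo2_series` for the two sites.
#' @param window,min_prominence Passed to [find_spo2_trough()].
#'
#' @return A `delay_result`: list with `per_hold` (tibble `hold`, `site`,
#'   `release_time_s`, `trough_time_s`, `delay_s`), `summary` (per-site
#'   `mean_delay_s`, `range_s`, `n_holds`) and `relative_delay_s`.
#'   Missing troughs are excluded from the means with a note; a site with
#'   no trough at all is an error.
#' @export
compute_delays <- function(events, spo2_ear, spo2_finger, window = 45,
                           min_prominence = 1) {
  if (nrow(events) < 1) abort_degenerate("no breath-hold events to analyse")
  series <- list(ear = spo2_ear, finger = spo2_finger)
  per_hold <- dplyr::bind_rows(lapply(c("ear", "finger"), function(site) {
    tt <- vapply(events$release_time_s, function(rt) {
      find_spo2_trough(series[[site]], rt, window, min_prominence)
    }, numeric(1))
    tibble(hold = events$hold, site = site,
           release_time_s = events$release_time_s,
           trough_time_s = tt, delay_s = tt - events$release_time_s)
  }))
  n_miss <- sum(is.na(per_hold$delay_s))
  if (n_miss > 0) {
    inform(sprintf("compute_delays: %d hold/site trough(s) not found; excluded from means",
                   n_miss))
  }
  summ <- per_hold |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(
      mean_delay_s = mean(.data$delay_s, na.rm = TRUE),
      range_s = if (any(!is.na(.data$delay_s)))
        diff(range(.data$delay_s, na.rm = TRUE)) else NA_real_,
      n_holds = sum(!is.na(.data$delay_s)),
      .groups = "drop"
    )
  if (any(summ$n_holds == 0)) {
    abort_degenerate(sprintf(
      "no SpO2 trough found for site(s): %s",
      paste(summ$site[summ$n_holds == 0], collapse = ", ")))
  }
  relative <- summ$mean_delay_s[summ$site == "finger"] -
    summ$mean_delay_s[summ$site == "ear"]
  structure(list(per_hold = per_hold, summary = summ,
                 relative_delay_s = relative),
            class = "delay_result")
}

#' @rdname compute_delays
#' @param x A `delay_result`.
#' @param ... Unused.
#' @export
tidy.delay_result <- function(x, ...) x$per_hold

#' @rdname compute_delays
#' @export
glance.delay_result <- function(x, ...) {
  s <- x$summary
  tibble(
    mean_delay_ear_s = s$mean_delay_s[s$site == "ear"],
    mean_delay_finger_s = s$mean_delay_s[s$site == "finger"],
    range_ear_s = s$range_s[s$site == "ear"],
    range_finger_s = s$range_s[s$site == "finger"],
    relative_delay_s = x$relative_delay_s,
    n_holds = min(s$n_holds)
  )
}

#' @export
print.delay_result <- function(x, ...) {
  cat(sprintf(
    "<delay_result> ear %.2f s, finger %.2f s, relative %.2f s over %d hold(s)\n",
    x$summary$mean_delay_s[x$summary$site == "ear"],
    x$summary$mean_delay_s[x$summary$site == "finger"],
    x$relative_delay_s, max(x$per_hold$hold)))
  invisible(x)
}
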