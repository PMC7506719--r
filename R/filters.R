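#' Isolate the pulsatile (AC) component of a raw PPG channel
#'
#' Zero-phase band-pass filter for extracting the cardiac-synchronous part of
#' a raw PPG signal, by default between 1 and 30 Hz. A 4th-order Butterworth
#' design is applied forward-backward ([signal::filtfilt()]) over a mirrored
#' (reflective) padding of the record so that start-up transients do not leak
#' into the output.
#'
#' @param x Numeric vector of raw ADC samples.
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz (defaults 1 and 30). If `high` is not
#'   below the Nyquist frequency it is reduced to `0.45 * fs` with a warning.
#'
#' @return Numeric vector, same length as `x`: the approximately zero-mean AC
#'   component.
#' @seealso [lowpass_dc()], [detect_extrema()]
#' @export
bandpass_ac <- function(x, fs, low = 1, high = 30) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort_format("`x` must be a finite numeric vector")
  }
  if (fs <= 0) abort_config("`fs` must be positive")
  if (high >= 0.5 * fs) {
    high <- 0.45 * fs
    warn(sprintf("upper band edge reduced to %.3g Hz (0.45 * fs)", high))
  }
  if (low <= 0 || low >= high) abort_config("need 0 < low < high < fs/2")
  n <- length(x)
  # one filter transient ~ 1/low seconds; require three of them
  n_min <- ceiling(3 * fs / low)
  if (n < n_min) {
    abort_degenerate(sprintf(
      "record too short for %g Hz high-pass edge: need >= %.1f s (%d samples), got %d",
      low, 3 / low, n_min, n
    ))
  }
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  # demean first: the filter state starts at zero, so removing the large DC
  # offset keeps start-up transients proportional to the AC excursion only
  filtfilt_padded(bf, x - mean(x), n_pad = min(n - 1L, ceiling(3 * fs / low)))
}

#' Estimate the slowly varying (DC) baseline of a raw PPG channel
#'
#' Low-pass filters a raw PPG signal at 0.01 Hz to obtain the non-pulsatile
#' baseline used as the denominator of the ratio of ratios. Because a 0.01 Hz
#' corner at typical PPG sampling rates is numerically ill-conditioned in
#' transfer-function form, the record is first block-mean decimated to ~1 Hz
#' (which also suppresses all cardiac content), filtered with a 2nd-order
#' zero-phase Butterworth over full mirrored padding, and linearly
#' interpolated back onto the original grid.
#'
#' @inheritParams bandpass_ac
#' @param cutoff Low-pass corner frequency in Hz (default 0.01).
#'
#' @return Numeric vector, same length as `x`. Records shorter than 60 s fall
#'   back to the record mean with a warning.
#' @export
lowpass_dc <- function(x, fs, cutoff = 0.01) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort_format("`x` must be a finite numeric vector")
  }
  if (fs <= 0) abort_config("`fs` must be positive")
  n <- length(x)
  if (n / fs < 60) {
    warn("record shorter than 60 s: DC baseline taken as the record mean")
    return(rep(mean(x), n))
  }
  m <- max(1L, as.integer(round(fs)))   # decimation factor -> ~1 Hz
  nb <- n %/% m
  xb <- colMeans(matrix(x[seq_len(nb * m)], nrow = m))
  tb <- (seq_len(nb) - 0.5) * m / fs    # block-centre times
  fs_d <- fs / m
  bf <- signal::butter(2, cutoff / (fs_d / 2))
  mu <- mean(xb)
  yb <- filtfilt_padded(bf, xb - mu, n_pad = nb - 1L) + mu
  t_full <- (seq_len(n) - 1) / fs
  approx(tb, yb, xout = t_full, rule = 2)$y
}

# zero-phase filtering with mirrored end padding
filtfilt_padded <- function(bf, x, n_pad) {
  n <- length(x)
  n_pad <- max(0L, min(as.integer(n_pad), n - 1L))
  if (n_pad > 0) {
    xp <- c(rev(x[seq(2, n_pad + 1)]), x, rev(x[seq(n - n_pad, n - 1)]))
  } else {
    xp <- x
  }
  y <- signal::filtfilt(bf, xp)
  y[seq(n_pad + 1, n_pad + n)]
}

# centred moving average with shrinking windows at the edges; NA-aware
moving_average <- function(x, k) {
  n <- length(x)
  if (k <= 1 || n == 0) return(x)
  half <- (as.integer(k) - 1L) %/% 2L
  ok <- is.finite(x)
  xs <- ifelse(ok, x, 0)
  cs <- cumsum(c(0, xs))
  cn <- cumsum(c(0, as.numeric(ok)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  tot <- cs[hi + 1] - cs[lo]
  cnt <- cn[hi + 1] - cn[lo]
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}
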