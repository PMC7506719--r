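#' Prominence-filtered peak and trough detection
#'
#' Finds local maxima of a signal whose topographic prominence reaches a
#' minimum threshold, and, by negating the signal, the corresponding troughs.
#' Prominence is the height of a peak above the higher of the two key saddles
#' separating it from higher terrain on each side (the window extends to the
#' record ends where no higher sample exists). The defaults used downstream
#' for PPG are 150 arbitrary ADC units for the infrared channel and 30 for
#' the red channel.
#'
#' @param x Numeric vector (typically a band-passed AC PPG trace).
#' @param fs Sampling rate in Hz, used to convert sample indices to times.
#' @param min_prominence Minimum topographic prominence, same units as `x`.
#' @param t0 Time of the first sample (seconds); defaults to 0.
#'
#' @return A list with tibbles `peaks` and `troughs`, each with columns
#'   `time_s`, `index`, `value`, `prominence` (prominence of the trough is
#'   measured on the negated signal). Either tibble may have zero rows.
#' @export
detect_extrema <- function(x, fs, min_prominence, t0 = 0) {
  if (length(min_prominence) != 1 || !is.finite(min_prominence) ||
      min_prominence <= 0) {
    abort_config("`min_prominence` must be a single positive number")
  }
  pk <- prominent_peaks(x, min_prominence)
  tr <- prominent_peaks(-x, min_prominence)
  list(
    peaks = tibble(time_s = t0 + (pk$index - 1) / fs, index = pk$index,
                   value = x[pk$index], prominence = pk$prominence),
    troughs = tibble(time_s = t0 + (tr$index - 1) / fs, index = tr$index,
                     value = x[tr$index], prominence = tr$prominence)
  )
}

# all local maxima of x with topographic prominence >= min_prominence.
# plateau maxima are reported at their rightmost sample.
prominent_peaks <- function(x, min_prominence) {
  p <- local_maxima(x)
  if (length(p) == 0) {
    return(list(index = integer(0), prominence = numeric(0)))
  }
  prom <- peak_prominences(x, p)
  keep <- prom >= min_prominence
  list(index = p[keep], prominence = prom[keep])
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (length(nz) < 2) return(integer(0))
  sv <- s[nz]
  # a peak: an up-step whose next non-flat step is a down-step
  turn <- which(sv[-length(sv)] > 0 & sv[-1] < 0)
  nz[turn + 1L]   # rightmost sample of any plateau
}

# topographic prominences for peak indices p (local maxima of x), via
# nearest-higher-peak bounds (monotonic stack) + range-minimum over the
# inter-peak valley minima; O(n + k log k).
peak_prominences <- function(x, p) {
  k <- length(p)
  h <- x[p]
  n <- length(x)
  # valley minima: V[1] before first peak, V[i+1] between peaks i and i+1,
  # V[k+1] after the last peak
  bounds_lo <- c(1L, p)
  bounds_hi <- c(p, n)
  V <- vapply(seq_len(k + 1L),
              function(i) min(x[bounds_lo[i]:bounds_hi[i]]),
              numeric(1))
  rmq <- rmq_build(V)

  left <- nearest_greater(h)            # 0 when none higher to the left
  ngr <- rev(nearest_greater(rev(h)))   # in reversed coordinates
  right <- ifelse(ngr == 0L, k + 1L, k + 1L - ngr)

  # min of signal between peak j (or record start) and peak i = min V[(j+1)..i]
  left_min <- rmq_query(rmq, left + 1L, seq_len(k))
  right_min <- rmq_query(rmq, seq_len(k) + 1L, right)
  h - pmax(left_min, right_min)
}

# for each i, index of the nearest j < i with h[j] > h[i]; 0 if none
nearest_greater <- function(h) {
  k <- length(h)
  res <- integer(k)
  stack <- integer(k)
  sp <- 0L
  for (i in seq_len(k)) {
    while (sp > 0L && h[stack[sp]] <= h[i]) sp <- sp - 1L
    res[i] <- if (sp > 0L) stack[sp] else 0L
    sp <- sp + 1L
    stack[sp] <- i
  }
  res
}

# sparse-table range minimum over a numeric vector
rmq_build <- function(v) {
  K <- length(v)
  L <- if (K > 1) floor(log2(K)) else 0
  tab <- matrix(NA_real_, nrow = L + 1L, ncol = K)
  tab[1L, ] <- v
  if (L > 0) {
    for (j in seq_len(L)) {
      len <- 2L^(j - 1L)
      upto <- K - 2L * len + 1L
      if (upto >= 1L) {
        tab[j + 1L, seq_len(upto)] <-
          pmin(tab[j, seq_len(upto)], tab[j, seq_len(upto) + len])
      }
    }
  }
  tab
}

# vectorised query: min v[a_i..b_i] (requires a <= b elementwise)
rmq_query <- function(tab, a, b) {
  len <- b - a + 1L
  j <- floor(log2(len))
  half <- 2L^j
  v1 <- tab[cbind(j + 1L, a)]
  v2 <- tab[cbind(j + 1L, b - half + 1L)]
  pmin(v1, v2)
}

#' Interpolated AC amplitude envelope from detected extrema
#'
#' Given the prominence-qualified peaks and troughs of a band-passed PPG
#' channel, interpolates the peak values and the trough values separately
#' onto the full record grid (linear interpolation, end-value hold beyond the
#' outermost extremum) and adds their absolute values to form a continuous
#' estimate of the AC (peak-to-peak) amplitude.
#'
#' @param extrema Result of [detect_extrema()].
#' @param time_s Full record time grid (seconds).
#' @param channel Channel name used in error messages.
#'
#' @return A tibble with columns `time_s`, `peak_env`, `trough_env`,
#'   `ac_amplitude`, where `ac_amplitude = |peak_env| + |trough_env|`.
#' @export
ac_envelope <- function(extrema, time_s, channel = "signal") {
  pk <- extrema$peaks
  tr <- extrema$troughs
  if (nrow(pk) < 2 || nrow(tr) < 2) {
    abort_degenerate(sprintf(
      "degenerate %s channel: need >= 2 peaks and >= 2 troughs (got %d / %d); check the prominence threshold",
      channel, nrow(pk), nrow(tr)
    ))
  }
  peak_env <- approx(pk$time_s, pk$value, xout = time_s, rule = 2)$y
  trough_env <- approx(tr$time_s, tr$value, xout = time_s, rule = 2)$y
  tibble(
    time_s = time_s,
    peak_env = peak_env,
    trough_env = trough_env,
    ac_amplitude = abs(peak_env) + abs(trough_env)
  )
}
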