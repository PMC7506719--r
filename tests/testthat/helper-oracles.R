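# Independent brute-force oracles used to validate the fast implementations.

# Topographic prominence by direct definition: for each local maximum, walk
# outwards to the nearest strictly higher sample (or the record end) on each
# side; the base on that side is the minimum in between; prominence is the
# peak height above the higher base.
brute_force_peaks <- function(x, min_prominence) {
  n <- length(x)
  idx <- integer(0)
  for (i in seq(2, n - 1)) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) {
      # rightmost sample of a plateau counts as the peak
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1
      if (j == n || x[j + 1] < x[i]) {
        if (j == i || x[i] > x[i - 1]) idx <- c(idx, j)
      }
    }
  }
  idx <- unique(idx)
  keep <- logical(length(idx))
  prom <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    h <- x[i]
    l <- i
    while (l > 1 && x[l - 1] <= h) l <- l - 1
    left_base <- min(x[max(1, l - 1):i])
    r <- i
    while (r < n && x[r + 1] <= h) r <- r + 1
    right_base <- min(x[i:min(n, r + 1)])
    prom[k] <- h - max(left_base, right_base)
    keep[k] <- prom[k] >= min_prominence
  }
  list(index = idx[keep], prominence = prom[keep])
}

# Button-event oracle: drop single-sample glitches, pair rising/falling
# edges, discard unmatched trailing edges and segments below the debounce
# threshold.
brute_force_events <- function(b, fs, min_duration = 2) {
  # remove isolated single-sample flips
  for (i in seq(2, length(b) - 1)) {
    if (b[i] != b[i - 1] && b[i] != b[i + 1]) b[i] <- b[i - 1]
  }
  t <- (seq_along(b) - 1) / fs
  rises <- which(diff(c(0, b)) == 1)
  falls <- which(diff(c(b, 0)) == -1)
  out <- data.frame(press = numeric(0), release = numeric(0))
  for (r in rises) {
    f <- falls[falls >= r][1]
    if (is.na(f) || f == length(b)) next
    press <- t[r]
    release <- t[f + 1]
    if (release - press >= min_duration) {
      out <- rbind(out, data.frame(press = press, release = release))
    }
  }
  out
}

# short constant-SpO2 trajectory on a uniform grid
flat_trajectory <- function(spo2, duration = 120, fs = 100) {
  n <- round(duration * fs)
  data.frame(time_s = (seq_len(n) - 1) / fs, spo2 = rep(spo2, n))
}
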