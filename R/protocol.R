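#' Build a breath-hold experiment timeline
#'
#' Constructs the staged breathing protocol used for dual-site desaturation
#' recordings: an initial rest, a number of exhale-then-hold manoeuvres
#' separated by rest periods, and a final rest. The defaults give the standard
#' 435 s session: 120 s rest, three repeats of 5 s exhale + 20 s breath hold
#' with 60 s rest between holds, and 120 s final rest. The exhale stage
#' precedes every hold so the desaturation is sharper than with a full-lung
#' hold.
#'
#' @param n_holds Number of exhale+hold manoeuvres (non-negative integer).
#' @param rest_pre Initial normal-breathing duration, seconds.
#' @param exhale Exhale duration before each hold, seconds.
#' @param hold Breath-hold duration, seconds.
#' @param rest_between Normal breathing between consecutive holds, seconds.
#' @param rest_post Final normal-breathing duration, seconds.
#'
#' @return A `ppg_protocol` tibble with one row per stage and columns
#'   `stage` (index), `label` (`"rest"`, `"exhale"` or `"hold"`),
#'   `duration_s`, `start_s`, `end_s`. The total duration is available via
#'   [protocol_duration()]; exhale-start / hold-end pairs via [hold_times()].
#'
#' @examples
#' timeline <- make_protocol()
#' protocol_duration(timeline) # 435
#' hold_times(timeline)
#' @export
make_protocol <- function(n_holds = 3, rest_pre = 120, exhale = 5, hold = 20,
                          rest_between = 60, rest_post = 120) {
  durs <- c(rest_pre, exhale, hold, rest_between, rest_post)
  if (any(!is.finite(durs)) || any(durs < 0)) {
    abort_config("all protocol stage durations must be finite and >= 0")
  }
  if (length(n_holds) != 1 || !is.finite(n_holds) || n_holds < 0 ||
      n_holds != round(n_holds)) {
    abort_config("`n_holds` must be a non-negative integer")
  }
  n_holds <- as.integer(n_holds)

  labels <- "rest"
  durations <- rest_pre
  if (n_holds > 0) {
    for (k in seq_len(n_holds)) {
      labels <- c(labels, "exhale", "hold")
      durations <- c(durations, exhale, hold)
      if (k < n_holds) {
        labels <- c(labels, "rest")
        durations <- c(durations, rest_between)
      }
    }
  }
  labels <- c(labels, "rest")
  durations <- c(durations, rest_post)

  keep <- durations > 0
  labels <- labels[keep]
  durations <- durations[keep]

  out <- tibble(
    stage = seq_along(labels),
    label = labels,
    duration_s = durations,
    start_s = cumsum(c(0, durations))[seq_along(durations)],
    end_s = cumsum(durations)
  )
  class(out) <- c("ppg_protocol", class(out))
  out
}

#' @rdname make_protocol
#' @param timeline A `ppg_protocol` object.
#' @export
protocol_duration <- function(timeline) {
  stopifnot(inherits(timeline, "ppg_protocol"))
  sum(timeline$duration_s)
}

#' @rdname make_protocol
#' @export
hold_times <- function(timeline) {
  stopifnot(inherits(timeline, "ppg_protocol"))
  ex <- which(timeline$label == "exhale")
  # each exhale is immediately followed by its hold
  hd <- ex + 1L
  bad <- hd > nrow(timeline) | timeline$label[pmin(hd, nrow(timeline))] != "hold"
  ex <- ex[!bad]
  hd <- hd[!bad]
  tibble(
    hold = seq_along(ex),
    exhale_start_s = timeline$start_s[ex],
    hold_start_s = timeline$start_s[hd],
    hold_end_s = timeline$end_s[hd]
  )
}

#' @export
print.ppg_protocol <- function(x, ...) {
  cat(sprintf("<ppg_protocol> %d stages, %g s total, %d breath hold(s)\n",
              nrow(x), sum(x$duration_s), sum(x$label == "hold")))
  NextMethod()
}
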