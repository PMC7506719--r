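#' Write and read PPG recordings as CSV + JSON sidecar
#'
#' A recording is stored as a plain CSV with header
#' `time_s,green,red,infrared,button` (the `green` column may be blank) and
#' a JSON sidecar `<name>.meta.json` carrying `format_version`, `fs` and the
#' subject metadata. Times are in seconds, 0-based at record start; the same
#' clock is used for every event time downstream.
#'
#' @param rec A [ppg_recording()].
#' @param path CSV path; the sidecar is written next to it.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a validated `ppg_recording` (invariant violations are fatal and
#'   name the offending field).
#' @export
write_recording <- function(rec, path) {
  validate_ppg_recording(rec)
  meta <- recording_meta(rec)
  readr::write_csv(as_tibble(rec)[, c("time_s", "green", "red", "infrared", "button")],
                   path, na = "")
  sidecar <- list(
    format_version = "1.0",
    fs = recording_fs(rec),
    subject_id = meta$subject_id, site = meta$site,
    sex = meta$sex, age = meta$age
  )
  jsonlite::write_json(sidecar, sidecar_path(path),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  sc <- sidecar_path(path)
  if (!file.exists(sc)) abort_format(sprintf("missing metadata sidecar: %s", sc))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$fs)) abort_format("fs: missing from metadata sidecar")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("time_s", "red", "infrared", "button")) {
    if (!col %in% names(df)) abort_format(sprintf("missing channel: %s", col))
  }
  if (!"green" %in% names(df)) df$green <- NA_real_
  ppg_recording(
    time_s = df$time_s, red = df$red, infrared = df$infrared,
    button = df$button, green = df$green, fs = meta$fs,
    subject_id = meta$subject_id %||% "unknown",
    site = meta$site %||% "ear",
    sex = meta$sex %||% NA_character_,
    age = meta$age %||% NA_real_
  )
}

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".meta.json")

#' Write and read cohort analysis results
#'
#' Serialises a [summarize_cohort()] result into a directory of flat CSV
#' tables (`per_subject.csv`, `delay_by_sex.csv`, `tests.csv`,
#' `correlations.csv`) plus `cohort.json` holding the cohort-level scalars
#' and a `format_version` field.
#'
#' @param summary A `cohort_summary`.
#' @param dir Output directory (created if needed).
#' @return `write_results` returns `dir` invisibly; `read_results` returns
#'   a list with the same tables and `scalars`.
#' @export
write_results <- function(summary, dir) {
  stopifnot(inherits(summary, "cohort_summary"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(summary$per_subject, file.path(dir, "per_subject.csv"))
  readr::write_csv(summary$delay_by_sex, file.path(dir, "delay_by_sex.csv"))
  readr::write_csv(summary$tests, file.path(dir, "tests.csv"))
  readr::write_csv(summary$correlations, file.path(dir, "correlations.csv"))
  jsonlite::write_json(c(list(format_version = "1.0"), summary$scalars),
                       file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @rdname write_results
#' @export
read_results <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) abort_format(sprintf("missing results table: %s", f))
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  }
  scal <- jsonlite::read_json(file.path(dir, "cohort.json"), simplifyVector = TRUE)
  list(
    per_subject = rd("per_subject.csv"),
    delay_by_sex = rd("delay_by_sex.csv"),
    tests = rd("tests.csv"),
    correlations = rd("correlations.csv"),
    scalars = scal[setdiff(names(scal), "format_version")]
  )
}
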