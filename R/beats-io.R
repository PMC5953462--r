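#' Read and write beat files
#'
#' A beat file is delimited text with header `time_s,rr_ms,r_amp` and one
#' row per beat: the beat time in seconds from recording start, the RR
#' interval ending at that beat in ms (empty for the first beat), and the
#' R-peak amplitude in arbitrary units. `read_beats()` validates the
#' structure and recomputes nothing: RR values are taken as stored, so a
#' write/read round trip reproduces the series to full precision. When the
#' `rr_ms` column is absent it is derived from consecutive beat times.
#'
#' @param path Path to a beat CSV file.
#' @param patient_id,label Optional metadata attached as attributes.
#' @return A tibble of class `beat_series` with columns `time_s`, `rr_ms`,
#'   `r_amp`.
#' @export
read_beats <- function(path, patient_id = NULL, label = "unknown") {
  if (!file.exists(path)) abort(sprintf("beat file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"time_s" %in% names(raw)) {
    abort(sprintf("beat file %s lacks required column 'time_s'", path))
  }
  if (!"r_amp" %in% names(raw)) {
    abort(sprintf("beat file %s lacks required column 'r_amp'", path))
  }
  if (!"rr_ms" %in% names(raw)) {
    raw$rr_ms <- c(NA_real_, diff(raw$time_s) * 1000)
  }
  new_beat_series(raw[c("time_s", "rr_ms", "r_amp")],
                  patient_id = patient_id %||% basename(path), label = label)
}

new_beat_series <- function(df, patient_id = NULL, label = "unknown") {
  df <- as_tibble(df)
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad)) {
    abort(sprintf(
      "beat times must be strictly increasing; first violation at row %d",
      bad[1] + 1L
    ))
  }
  if (any(df$rr_ms[-1] <= 0, na.rm = TRUE)) {
    abort("RR intervals must be positive")
  }
  structure(df,
    class = c("beat_series", class(df)),
    patient_id = patient_id, label = label
  )
}

#' @rdname read_beats
#' @param series A `beat_series` (or compatible data frame).
#' @export
write_beats <- function(series, path) {
  readr::write_csv(as_tibble(series)[c("time_s", "rr_ms", "r_amp")], path)
  invisible(path)
}

#' Read a protocol segmentation file
#'
#' The segmentation file is a one-row CSV with the five protocol
#' timestamps, in seconds from recording start: `warmup_start_s`,
#' `exercise_start_s`, `peak_effort_s`, `active_rec_end_s`,
#' `passive_rec_end_s`.
#'
#' @param path Path to the segmentation CSV.
#' @return A one-row tibble with the five timestamps, validated to be
#'   strictly increasing.
#' @export
read_segmentation <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("segmentation file not found: %s", path))
  }
  seg <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("warmup_start_s", "exercise_start_s", "peak_effort_s",
            "active_rec_end_s", "passive_rec_end_s")
  missing <- setdiff(need, names(seg))
  if (length(missing)) {
    abort(sprintf("segmentation file %s lacks column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  validate_segmentation(seg[need])
}

validate_segmentation <- function(seg) {
  v <- as.numeric(seg[1, c("warmup_start_s", "exercise_start_s",
                           "peak_effort_s", "active_rec_end_s",
                           "passive_rec_end_s")])
  if (any(diff(v) <= 0)) {
    abort("segmentation timestamps must be strictly increasing")
  }
  as_tibble(seg)
}
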