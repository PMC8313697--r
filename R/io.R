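# Reading and writing the package's data dialects: trial-table CSV and
# per-pulse EMG sweep CSV with a JSON metadata sidecar.

trial_table_columns <- c("participant_id", "block", "trial", "phase",
                         "trial_type", "direction", "ssd_ms", "response",
                         "rt_ms", "correct")

#' Validate a trial table against the dialect
#'
#' @param trials A `data.frame`.
#' @return The table, invisibly, or an error naming offending rows.
#' @keywords internal
#' @noRd
validate_trial_table <- function(trials) {
  missing_cols <- setdiff(trial_table_columns, names(trials))
  if (length(missing_cols)) {
    stop("trial table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad_type <- which(!trials$trial_type %in% c("go", "stop"))
  if (length(bad_type)) {
    stop("invalid trial_type at row(s): ",
         paste(utils::head(bad_type, 5), collapse = ", "))
  }
  bad_phase <- which(!trials$phase %in% c("practice", "experimental"))
  if (length(bad_phase)) {
    stop("invalid phase at row(s): ",
         paste(utils::head(bad_phase, 5), collapse = ", "))
  }
  bad_resp <- which(!trials$response %in% c("left", "right", "none"))
  if (length(bad_resp)) {
    stop("invalid response at row(s): ",
         paste(utils::head(bad_resp, 5), collapse = ", "))
  }
  if (!is.numeric(trials$ssd_ms) || !is.numeric(trials$rt_ms)) {
    stop("ssd_ms and rt_ms must be numeric")
  }
  no_ssd <- which(trials$trial_type == "stop" & is.na(trials$ssd_ms))
  if (length(no_ssd)) {
    stop("stop trial without an SSD at row(s): ",
         paste(utils::head(no_ssd, 5), collapse = ", "))
  }
  bad_rt <- which(!is.na(trials$rt_ms) & trials$rt_ms <= 0)
  if (length(bad_rt)) {
    stop("non-positive RT at row(s): ",
         paste(utils::head(bad_rt, 5), collapse = ", "))
  }
  invisible(trials)
}

#' Write / read a trial table as CSV
#'
#' The dialect is the column set produced by [simulate_session()], with empty
#' fields for missing SSDs (go trials) and RTs (omissions). Reading validates
#' the schema strictly and reports offending row numbers.
#'
#' @param trials A trial table `data.frame`.
#' @param path File path.
#' @return `write_trial_table` returns `path` invisibly; `read_trial_table`
#'   returns the validated `data.frame`.
#' @export
write_trial_table <- function(trials, path) {
  validate_trial_table(trials)
  out <- trials[, trial_table_columns]
  for (col in c("ssd_ms", "rt_ms")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         formatC(out[[col]], digits = 15, format = "g"))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- names(utils::read.csv(path, nrows = 0L))
  missing_cols <- setdiff(trial_table_columns, hdr)
  if (length(missing_cols)) {
    stop("trial table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(
                           participant_id = "character", block = "integer",
                           trial = "integer", phase = "character",
                           trial_type = "character", direction = "character",
                           ssd_ms = "numeric", response = "character",
                           rt_ms = "numeric", correct = "integer"))
  validate_trial_table(tab)
  tab
}

#' Write / read one EMG sweep as CSV plus a JSON sidecar
#'
#' The sweep is a two-column CSV (`time_ms`, `emg_mv`); the sidecar records
#' `fs_hz`, `stim_time_ms`, `participant_id`, `pulse_index`,
#' `stim_intensity_pct_rmt` and `rmt_pct_mso`.
#'
#' @param trace An [emg_trace()].
#' @param csv_path CSV path; the sidecar defaults to the same path with a
#'   `.json` extension.
#' @param json_path Optional sidecar path.
#' @return `write_emg_sweep` returns `csv_path` invisibly; `read_emg_sweep`
#'   returns an [emg_trace()].
#' @export
write_emg_sweep <- function(trace, csv_path, json_path = NULL) {
  stopifnot(inherits(trace, "emg_trace"))
  if (is.null(json_path)) json_path <- sub("\\.csv$", ".json", csv_path)
  t_ms <- (seq_along(trace$samples) - 1) / trace$fs * 1000
  utils::write.csv(
    data.frame(time_ms = formatC(t_ms, digits = 10, format = "g"),
               emg_mv = formatC(trace$samples, digits = 15, format = "g")),
    csv_path, row.names = FALSE, quote = FALSE)
  side <- list(
    fs_hz = trace$fs, stim_time_ms = trace$stim_time,
    participant_id = trace$metadata$participant_id %||% NA,
    pulse_index = trace$metadata$pulse_index %||% NA,
    stim_intensity_pct_rmt = trace$metadata$stim_intensity_pct_rmt %||% 120,
    rmt_pct_mso = trace$metadata$rmt_pct_mso %||% NA
  )
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(csv_path)
}

#' @rdname write_emg_sweep
#' @export
read_emg_sweep <- function(csv_path, json_path = NULL) {
  if (is.null(json_path)) json_path <- sub("\\.csv$", ".json", csv_path)
  if (!file.exists(csv_path)) stop("file not found: ", csv_path)
  if (!file.exists(json_path)) stop("sidecar not found: ", json_path)
  dat <- utils::read.csv(csv_path, colClasses = "numeric")
  if (!all(c("time_ms", "emg_mv") %in% names(dat))) {
    stop("sweep CSV must have columns time_ms, emg_mv")
  }
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  for (f in c("fs_hz", "stim_time_ms")) {
    if (is.null(side[[f]])) stop("sidecar missing field: ", f)
  }
  emg_trace(dat$emg_mv, fs = side$fs_hz, stim_time = side$stim_time_ms,
            metadata = side[setdiff(names(side), c("fs_hz", "stim_time_ms"))])
}
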