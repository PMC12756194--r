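sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Write a voltage trace to CSV with a JSON sidecar
#'
#' The CSV has header `time_s,voltage_uV`, times in seconds to 6 decimals
#' and voltages in microvolts to 3 decimals (comma separator, `.` decimal,
#' UTF-8, LF). Metadata (`fs_hz`, `condition`, `day_index`, `seed`,
#' `units = "uV"`) goes to a sidecar of the same name with extension
#' `.json`.
#'
#' @param trace A [voltage_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  fs <- trace_fs(trace)
  out <- tibble(time_s = round(trace$time_s, 6),
                voltage_uV = round(trace$voltage_uV, 3))
  readr::write_csv(out, path, eol = "\n", progress = FALSE)
  meta <- list(fs_hz = fs,
               condition = attr(trace, "condition") %||% NA_character_,
               day_index = attr(trace, "day_index") %||% NA_integer_,
               seed = attr(trace, "seed") %||% NA_integer_,
               units = "uV")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a voltage trace from CSV + JSON sidecar
#'
#' Validates that the sidecar exists, that units are microvolts (`"uV"`,
#' no silent rescaling) and that the time column is uniform at `fs_hz`
#' (relative jitter below 1e-6). Each failure mode carries a distinct
#' condition class (`cyanospike_error_missing_sidecar`,
#' `cyanospike_error_bad_units`, `cyanospike_error_nonuniform_sampling`).
#'
#' @param path CSV path written by [write_trace()] (or hand-built to the
#'   same contract).
#' @return A [voltage_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    stop_cyanospike("io", sprintf("trace file not found: %s", path))
  }
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop_cyanospike("missing_sidecar",
                    sprintf("sidecar metadata file not found: %s", sc))
  }
  meta <- jsonlite::read_json(sc)
  if (is.null(meta$units) || !identical(meta$units, "uV")) {
    stop_cyanospike("bad_units",
                    sprintf("sidecar units must be \"uV\", got %s",
                            meta$units %||% "<missing>"))
  }
  if (is.null(meta$fs_hz) || !is.numeric(meta$fs_hz) || meta$fs_hz <= 0) {
    stop_cyanospike("bad_param", "sidecar must carry a positive numeric fs_hz")
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(), voltage_uV = readr::col_double()
  ), progress = FALSE)
  if (!all(c("time_s", "voltage_uV") %in% names(df))) {
    stop_cyanospike("io", "trace CSV must have columns time_s and voltage_uV")
  }
  fs <- as.numeric(meta$fs_hz)
  if (nrow(df) > 1) {
    dt <- diff(df$time_s)
    # relative deviation of every sample interval from 1/fs; 6-decimal
    # serialization keeps this at ~1e-3 * fs in the worst case, so compare
    # against the serialization granularity too
    jitter <- abs(dt * fs - 1)
    tol <- max(1e-6, 2e-6 * fs) # 1e-6 s written precision, two endpoints
    if (any(jitter > tol)) {
      stop_cyanospike("nonuniform_sampling",
                      sprintf("time column is not uniform at fs = %g Hz (max relative jitter %.3g)",
                              fs, max(jitter)))
    }
  }
  voltage_trace(df$voltage_uV, fs,
                condition = meta$condition %||% NA_character_,
                day_index = meta$day_index %||% NA_integer_,
                seed = meta$seed %||% NA_integer_)
}

#' Write / read detected or ground-truth events
#'
#' CSV columns, in fixed order: `onset_s` (6 decimals), `class`,
#' `amplitude_uV` (3 decimals), `duration_s` (6 decimals). Events must be
#' sorted by onset.
#'
#' @param events An event tibble with columns `onset_s`, `event_class`,
#'   `peak_amp_uv`, `duration_s`.
#' @param path Output CSV path.
#' @return `path` (writer) or the event tibble (reader).
#' @export
write_events <- function(events, path) {
  events <- as_tibble(events)
  if (nrow(events) > 1 && is.unsorted(events$onset_s)) {
    stop_cyanospike("unsorted_events", "events must be sorted by `onset_s`")
  }
  out <- tibble(onset_s = round(events$onset_s, 6),
                class = events$event_class,
                amplitude_uV = round(events$peak_amp_uv, 3),
                duration_s = round(events$duration_s, 6))
  readr::write_csv(out, path, eol = "\n", progress = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    onset_s = readr::col_double(), class = readr::col_character(),
    amplitude_uV = readr::col_double(), duration_s = readr::col_double()
  ), progress = FALSE)
  tibble(onset_s = df$onset_s, event_class = df$class,
         peak_amp_uv = df$amplitude_uV, duration_s = df$duration_s)
}

summary_columns <- function() {
  c("condition", "freq_q2", "freq_iqr_lo", "freq_iqr_hi", "freq_q4",
    "amp_q2", "amp_iqr_lo", "amp_iqr_hi", "amp_q4")
}

#' Write / read a per-condition quartile summary table
#'
#' Columns mirror the daily-median readout: `condition`, frequency quartiles
#' (`freq_q2`, `freq_iqr_lo`, `freq_iqr_hi`, `freq_q4`) and amplitude
#' quartiles (`amp_q2`, `amp_iqr_lo`, `amp_iqr_hi`, `amp_q4`).
#'
#' @param rows A summary tibble (see [quartile_summary()]).
#' @param path Output CSV path.
#' @return `path` (writer) or the summary tibble (reader).
#' @export
write_summary <- function(rows, path) {
  rows <- as_tibble(rows)
  missing <- setdiff(summary_columns(), names(rows))
  if (length(missing)) {
    stop_cyanospike("bad_param",
                    sprintf("summary is missing column(s): %s",
                            paste(missing, collapse = ", ")))
  }
  out <- rows[, summary_columns()]
  num <- setdiff(summary_columns(), "condition")
  out[num] <- lapply(out[num], function(x) round(x, 3))
  readr::write_csv(out, path, eol = "\n", progress = FALSE)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    condition = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
}
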