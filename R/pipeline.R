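#' Analyse one voltage trace end to end
#'
#' Baseline removal, band split, robust noise-scale estimation, fast-spike
#' detection, RTS segmentation and event classification, followed by the
#' per-minute rate series and the quartile summary when the trace is at
#' least one minute long.
#'
#' @param trace A [voltage_trace()].
#' @param config A [detection_config()].
#' @return An object of class `trace_analysis`: a list with `events`
#'   (classified event tibble), `per_minute` (tumbling-window counts or
#'   `NULL` for traces under a minute), `summary` (one-row
#'   [quartile_summary()] or `NULL`), `sigma`, `rts`
#'   (the `rts_segmentation`), `condition`, `duration_s` and `config`.
#'   Supports [tidy()] (events) and [glance()] (one-row overview).
#' @export
analyze_trace <- function(trace, config = detection_config()) {
  prepped <- split_bands(remove_baseline(trace, config$baseline_window_s),
                         config$fc_hz)
  sigma <- noise_sigma(prepped)
  spikes <- detect_spikes(prepped, sigma, config)
  rts <- segment_rts(prepped, config)
  events <- merge_and_classify(spikes, rts, config)
  duration_s <- trace_duration(trace)
  per_minute <- NULL
  summary <- NULL
  if (duration_s >= 60) {
    rate_events <- filter_classes(events, config$rate_classes)
    amp_events <- filter_classes(events, config$amp_classes)
    per_minute <- events_per_minute(rate_events, duration_s)
    summary <- quartile_summary(per_minute, amp_events$peak_amp_uv,
                                condition = attr(trace, "condition"))
  }
  structure(list(events = events, per_minute = per_minute, summary = summary,
                 sigma = sigma, rts = rts,
                 condition = attr(trace, "condition"),
                 duration_s = duration_s, config = config),
            class = "trace_analysis")
}

filter_classes <- function(events, which) {
  if (identical(which, "fast")) {
    events[events$event_class == "fast_spike", , drop = FALSE]
  } else {
    events
  }
}

#' @export
print.trace_analysis <- function(x, ...) {
  cat(sprintf("<trace_analysis> %s: %.0f s, sigma %.3f uV, %d fast spike(s), %d RTS step(s)%s\n",
              x$condition %||% "?", x$duration_s, x$sigma,
              sum(x$events$event_class == "fast_spike"),
              sum(x$events$event_class == "rts_step"),
              if (x$rts$no_rts) " [no RTS detected]" else ""))
  invisible(x)
}

#' @rdname analyze_trace
#' @param x A `trace_analysis`.
#' @param ... Unused.
#' @export
tidy.trace_analysis <- function(x, ...) {
  x$events
}

#' @rdname analyze_trace
#' @export
glance.trace_analysis <- function(x, ...) {
  base <- tibble(condition = x$condition %||% NA_character_,
                 duration_s = x$duration_s, sigma_uv = x$sigma,
                 n_fast = sum(x$events$event_class == "fast_spike"),
                 n_rts = sum(x$events$event_class == "rts_step"),
                 no_rts = x$rts$no_rts)
  if (!is.null(x$summary)) {
    base$freq_q2 <- x$summary$freq_q2
    base$amp_q2 <- x$summary$amp_q2
  }
  base
}

#' Run the full simulate-or-analyze pipeline
#'
#' `mode = "simulate"` synthesizes the schedule, analyses every condition
#' and writes (per condition) the trace CSV + sidecar, ground-truth and
#' detected event CSVs, then the summary CSV, the repletion-contrast JSON
#' (when the required conditions are present) and a reproducibility
#' manifest with per-file checksums. `mode = "analyze"` does the same from
#' existing trace files. Idempotent for a fixed seed and config.
#'
#' @param mode `"simulate"` or `"analyze"`.
#' @param out_dir Output directory (created if needed).
#' @param schedule A [condition_schedule()] (simulate mode).
#' @param trace_paths Character vector of trace CSV paths (analyze mode).
#' @param config A [detection_config()].
#' @param fs_hz Sampling frequency for simulation.
#' @param seed Master seed for simulation.
#' @param write_traces Write simulated trace CSVs (they dominate output
#'   size; disable for summary-only runs).
#' @param quiet Suppress stage logging.
#' @return Invisibly, a list with `summary`, `contrast`, `analyses`,
#'   `manifest_path` and `files`.
#' @export
run_pipeline <- function(mode = c("simulate", "analyze"), out_dir,
                         schedule = default_schedule(), trace_paths = NULL,
                         config = detection_config(), fs_hz = 2000,
                         seed = 1L, write_traces = TRUE, quiet = FALSE) {
  mode <- match.arg(mode)
  if (missing(out_dir) || !is.character(out_dir) || length(out_dir) != 1) {
    stop_cyanospike("bad_config", "`out_dir` must be a single path")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) {
    if (!quiet) inform(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%OS1"),
                               sprintf(...)))
  }
  files <- character(0)
  keep <- function(path) { files[[length(files) + 1L]] <<- path; path }

  if (mode == "simulate") {
    log_stage("simulating %d condition(s), fs = %g Hz, seed = %d",
              length(schedule), fs_hz, seed)
    sim <- synthesize_schedule(schedule, fs_hz = fs_hz, seed = seed)
    traces <- sim$trace
    conditions <- sim$condition
    for (i in seq_len(nrow(sim))) {
      slug <- condition_slug(sim$condition[i])
      if (write_traces) {
        keep(write_trace(sim$trace[[i]],
                         file.path(out_dir, paste0("trace_", slug, ".csv"))))
        keep(sidecar_path(file.path(out_dir, paste0("trace_", slug, ".csv"))))
      }
      keep(write_events(sim$events[[i]],
                        file.path(out_dir, paste0("truth_", slug, ".csv"))))
    }
  } else {
    if (is.null(trace_paths) || length(trace_paths) < 1) {
      stop_cyanospike("bad_config", "analyze mode requires at least one trace path")
    }
    log_stage("reading %d trace(s)", length(trace_paths))
    traces <- lapply(trace_paths, read_trace)
    conditions <- vapply(traces, function(tr) attr(tr, "condition"), character(1))
  }

  analyses <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    log_stage("analysing condition %s", conditions[i])
    analyses[[i]] <- analyze_trace(traces[[i]], config)
    keep(write_events(analyses[[i]]$events,
                      file.path(out_dir,
                                paste0("events_", condition_slug(conditions[i]), ".csv"))))
    if (nrow(analyses[[i]]$events) == 0) {
      warn(sprintf("no events detected in condition %s", conditions[i]),
           class = "cyanospike_warning_empty_detection")
    }
  }
  names(analyses) <- conditions

  summaries <- purrr::compact(lapply(analyses, function(a) a$summary))
  summary_tab <- NULL
  contrast <- NULL
  if (length(summaries)) {
    summary_tab <- build_summary_table(bind_rows(summaries))
    keep(write_summary(summary_tab, file.path(out_dir, "summary.csv")))
    if (all(c("-Nd1", "-Nd4", "NH4+d1", "NH4+d2") %in% summary_tab$condition)) {
      contrast <- repletion_response(summary_tab)
      jsonlite::write_json(as.list(contrast),
                           keep(file.path(out_dir, "contrast.json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  manifest <- list(
    package = "cyanospike",
    version = as.character(packageVersion("cyanospike")),
    mode = mode, seed = if (mode == "simulate") seed else NA,
    fs_hz = if (mode == "simulate") fs_hz else NA,
    config = unclass(config),
    files = lapply(sort(unique(files)), function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  log_stage("wrote %d file(s) to %s", length(files) + 1L, out_dir)
  invisible(list(summary = summary_tab, contrast = contrast,
                 analyses = analyses, manifest_path = manifest_path,
                 files = files))
}

condition_slug <- function(label) {
  gsub("[^A-Za-z0-9]+", "", label)
}
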