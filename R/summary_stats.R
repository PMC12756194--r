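#' Per-minute event counts over tumbling windows
#'
#' Counts events in non-overlapping 1-minute windows anchored at t = 0; a
#' trailing partial window is dropped. Tumbling (not sliding) windows keep
#' the per-window counts independent and match an events-per-minute readout
#' literally.
#'
#' @param events An event tibble (uses `onset_s`).
#' @param duration_s Recording duration in seconds (>= 60).
#' @return A tibble with `minute` (1-based window index) and `count`.
#' @export
events_per_minute <- function(events, duration_s) {
  check_number(duration_s, "duration_s", min = 60)
  n_win <- floor(duration_s / 60)
  onset <- events$onset_s
  onset <- onset[onset >= 0 & onset < n_win * 60]
  counts <- tabulate(floor(onset / 60) + 1L, nbins = n_win)
  tibble(minute = seq_len(n_win), count = counts)
}

#' Quartile summary of rates and amplitudes for one condition
#'
#' The daily readout: median (Q2), 25th/75th percentiles (IQR bounds,
#' linear interpolation between order statistics) and observed maximum (Q4)
#' of the per-minute counts and of the event amplitudes.
#'
#' @param counts Numeric vector of per-minute counts (or the tibble from
#'   [events_per_minute()]).
#' @param amplitudes Numeric vector of event amplitudes in microvolts; may
#'   be empty, in which case the amplitude block is zero and flagged.
#' @param condition Condition label for the row.
#' @return A one-row tibble with the nine summary columns plus `n_minutes`,
#'   `n_events` and `amp_empty`.
#' @export
quartile_summary <- function(counts, amplitudes, condition = NA_character_) {
  if (is.data.frame(counts)) counts <- counts$count
  if (length(counts) == 0) {
    stop_cyanospike("bad_param", "`counts` must be non-empty")
  }
  fq <- quartiles4(counts)
  aq <- if (length(amplitudes) > 0) quartiles4(amplitudes) else rep(0, 4)
  tibble(condition = condition,
         freq_q2 = fq[2], freq_iqr_lo = fq[1], freq_iqr_hi = fq[3],
         freq_q4 = fq[4],
         amp_q2 = aq[2], amp_iqr_lo = aq[1], amp_iqr_hi = aq[3],
         amp_q4 = aq[4],
         n_minutes = length(counts), n_events = length(amplitudes),
         amp_empty = length(amplitudes) == 0)
}

# (q25, q50, q75, max); type 7 = linear interpolation between order stats
quartiles4 <- function(x) {
  c(unname(quantile(x, c(0.25, 0.5, 0.75), type = 7)), max(x))
}

#' Assemble per-condition summaries into the six-day table
#'
#' Rows are returned in experimental order (`-Nd1` ... `NH4+d2`) regardless
#' of input order; unknown condition labels are rejected.
#'
#' @param summaries A list of one-row summaries from [quartile_summary()],
#'   or a tibble of such rows.
#' @return The ordered summary tibble.
#' @export
build_summary_table <- function(summaries) {
  tab <- if (is.data.frame(summaries)) as_tibble(summaries) else bind_rows(summaries)
  if (nrow(tab) < 1) {
    stop_cyanospike("bad_param", "at least one condition summary is required")
  }
  bad <- setdiff(tab$condition, condition_labels())
  if (length(bad)) {
    stop_cyanospike("unknown_condition",
                    sprintf("unknown condition label(s): %s",
                            paste(bad, collapse = ", ")))
  }
  tab[order(match(tab$condition, condition_labels())), , drop = FALSE]
}

#' Starvation-to-repletion contrast
#'
#' Quantifies how activity falls after ammonium repletion: median-rate and
#' median-amplitude ratios of each repletion day to the last starvation day,
#' plus two boolean flags - `decline_24h` (repletion day 1 median rate below
#' starvation day 4) and `near_baseline_48h` (repletion day 2 median rate
#' within 1 event/min of starvation day 1).
#'
#' @param summary_table Summary tibble containing rows for `-Nd1`, `-Nd4`,
#'   `NH4+d1` and `NH4+d2`.
#' @return A one-row tibble: `freq_ratio_24h`, `freq_ratio_48h`,
#'   `amp_ratio_24h`, `amp_ratio_48h`, `decline_24h`, `near_baseline_48h`.
#' @export
repletion_response <- function(summary_table) {
  need <- c("-Nd1", "-Nd4", "NH4+d1", "NH4+d2")
  missing <- setdiff(need, summary_table$condition)
  if (length(missing)) {
    stop_cyanospike("missing_condition",
                    sprintf("summary table lacks required condition(s): %s",
                            paste(missing, collapse = ", ")))
  }
  row <- function(cond) summary_table[summary_table$condition == cond, ][1, ]
  d1 <- row("-Nd1"); d4 <- row("-Nd4")
  r1 <- row("NH4+d1"); r2 <- row("NH4+d2")
  tibble(
    freq_ratio_24h = r1$freq_q2 / d4$freq_q2,
    freq_ratio_48h = r2$freq_q2 / d4$freq_q2,
    amp_ratio_24h = r1$amp_q2 / d4$amp_q2,
    amp_ratio_48h = r2$amp_q2 / d4$amp_q2,
    decline_24h = r1$freq_q2 < d4$freq_q2,
    near_baseline_48h = r2$freq_q2 <= d1$freq_q2 + 1
  )
}
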