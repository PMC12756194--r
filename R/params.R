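#' Canonical condition labels of the six-day starvation/repletion course
#'
#' Four days of nitrogen starvation (`-Nd1` ... `-Nd4`) followed by two days
#' after ammonium repletion (`NH4+d1`, `NH4+d2`). ASCII hyphens are used so
#' labels are safe in file names and CSV headers.
#'
#' @return Character vector of the six labels, in experimental order.
#' @export
condition_labels <- function() {
  c("-Nd1", "-Nd2", "-Nd3", "-Nd4", "NH4+d1", "NH4+d2")
}

#' Fast-spike generator parameters
#'
#' Describes the millisecond-scale, high-amplitude event class: a homogeneous
#' Poisson train of smooth unimodal pulses with log-normally distributed peak
#' amplitude.
#'
#' @param rate_per_min Mean event rate, events per minute (>= 0).
#' @param amp_median_uv Median peak amplitude in microvolts (> 0).
#' @param amp_spread Log-scale standard deviation of the amplitude law (>= 0).
#' @param width_ms Full pulse width in milliseconds, in (0.5, 50) so the
#'   class stays on the millisecond scale.
#' @param polarity_prob_pos Probability that a pulse deflects positive.
#' @return A list of class `spike_params`.
#' @export
spike_params <- function(rate_per_min = 1, amp_median_uv = 3.5,
                         amp_spread = 0.5, width_ms = 5,
                         polarity_prob_pos = 0.5) {
  check_number(rate_per_min, "rate_per_min", min = 0)
  check_number(amp_median_uv, "amp_median_uv", min = 0, strict_min = TRUE)
  check_number(amp_spread, "amp_spread", min = 0)
  check_number(width_ms, "width_ms", min = 0.5, max = 50,
               strict_min = TRUE, strict_max = TRUE)
  check_number(polarity_prob_pos, "polarity_prob_pos", min = 0, max = 1)
  structure(list(rate_per_min = rate_per_min, amp_median_uv = amp_median_uv,
                 amp_spread = amp_spread, width_ms = width_ms,
                 polarity_prob_pos = polarity_prob_pos),
            class = "spike_params")
}

#' Random-telegraph-signal generator parameters
#'
#' Two-level process switching low -> high at rate `k_up` and high -> low at
#' rate `k_down`, with exponential dwell times; mean high-state dwell is
#' `1/k_down`.
#'
#' @param k_up Low-to-high transition rate, 1/s (>= 0).
#' @param k_down High-to-low transition rate, 1/s (>= 0).
#' @param step_uv Level separation in microvolts (> 0).
#' @return A list of class `rts_params`.
#' @export
rts_params <- function(k_up = 0.005, k_down = 0.5, step_uv = 6) {
  check_number(k_up, "k_up", min = 0)
  check_number(k_down, "k_down", min = 0)
  check_number(step_uv, "step_uv", min = 0, strict_min = TRUE)
  structure(list(k_up = k_up, k_down = k_down, step_uv = step_uv),
            class = "rts_params")
}

#' Recording-noise generator parameters
#'
#' White Gaussian noise plus a 1/f-shaped component plus a deterministic
#' linear baseline drift. With all fields zero the generated noise is
#' identically zero.
#'
#' @param white_sd_uv Standard deviation of the white component, microvolts.
#' @param pink_sd_uv Standard deviation of the 1/f component, microvolts.
#' @param drift_uv_per_min Linear drift slope, microvolts per minute (may be
#'   negative).
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(white_sd_uv = 0.2, pink_sd_uv = 0.3,
                         drift_uv_per_min = 0.5) {
  check_number(white_sd_uv, "white_sd_uv", min = 0)
  check_number(pink_sd_uv, "pink_sd_uv", min = 0)
  check_number(drift_uv_per_min, "drift_uv_per_min")
  structure(list(white_sd_uv = white_sd_uv, pink_sd_uv = pink_sd_uv,
                 drift_uv_per_min = drift_uv_per_min),
            class = "noise_params")
}

#' Detection configuration
#'
#' All thresholds and time constants used by preprocessing, spike detection,
#' RTS segmentation and event classification. Serves as the reproducibility
#' contract: a config plus a seed fully determines a pipeline run.
#'
#' @param k_sigma Threshold multiplier on the robust noise scale (default 5,
#'   the conservative convention for extracellular recordings).
#' @param refractory_ms Supra-threshold excursions closer than this are
#'   merged into one event (ms).
#' @param class_boundary_s Duration separating the millisecond spike class
#'   from the seconds-scale RTS class (s). Must be < `min_dwell_s`.
#' @param min_dwell_s Minimum credited RTS dwell; shorter runs are merged
#'   into their longer neighbour (s).
#' @param fc_hz Corner frequency of the zero-phase band split (Hz).
#' @param baseline_window_s Running-median window for baseline removal (s).
#' @param edge_guard_s Fast-band events whose peak lies within this window of
#'   a segmented RTS transition are treated as filter edge artifacts of the
#'   step, not biological spikes, and absorbed into the step event (s).
#' @param rate_classes Which event classes enter the headline per-minute
#'   rate: `"fast"` (default) or `"all"`.
#' @param amp_classes Which classes are pooled for amplitude statistics:
#'   `"all"` (default) or `"fast"`.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(k_sigma = 5, refractory_ms = 20,
                             class_boundary_s = 0.1, min_dwell_s = 0.5,
                             fc_hz = 10, baseline_window_s = 60,
                             edge_guard_s = 0.05,
                             rate_classes = c("fast", "all"),
                             amp_classes = c("all", "fast")) {
  check_number(k_sigma, "k_sigma", min = 0, strict_min = TRUE)
  check_number(refractory_ms, "refractory_ms", min = 0, strict_min = TRUE)
  check_number(class_boundary_s, "class_boundary_s", min = 0, strict_min = TRUE)
  check_number(min_dwell_s, "min_dwell_s", min = 0, strict_min = TRUE)
  check_number(fc_hz, "fc_hz", min = 0, strict_min = TRUE)
  check_number(baseline_window_s, "baseline_window_s", min = 0, strict_min = TRUE)
  check_number(edge_guard_s, "edge_guard_s", min = 0)
  if (class_boundary_s >= min_dwell_s) {
    stop_cyanospike("bad_config",
                    "`class_boundary_s` must be smaller than `min_dwell_s`")
  }
  structure(list(k_sigma = k_sigma, refractory_ms = refractory_ms,
                 class_boundary_s = class_boundary_s,
                 min_dwell_s = min_dwell_s, fc_hz = fc_hz,
                 baseline_window_s = baseline_window_s,
                 edge_guard_s = edge_guard_s,
                 rate_classes = match.arg(rate_classes),
                 amp_classes = match.arg(amp_classes)),
            class = "detection_config")
}

#' Calibration targets for the default six-day course
#'
#' Per-condition daily medians and quartiles (per-minute event rate and event
#' amplitude) to which the default synthetic schedule is calibrated: rates
#' rise over the four starvation days, peak on day 4, and fall back toward
#' baseline within two days of ammonium repletion.
#'
#' @return A tibble with one row per condition: `condition`, `day_index`,
#'   frequency quartiles (`freq_q2`, `freq_iqr_lo`, `freq_iqr_hi`, `freq_q4`,
#'   events/min) and amplitude quartiles (`amp_q2`, `amp_iqr_lo`,
#'   `amp_iqr_hi`, `amp_q4`, microvolts).
#' @export
schedule_targets <- function() {
  tibble(
    condition   = condition_labels(),
    day_index   = 1:6,
    freq_q2     = c(1, 2, 1, 5, 3, 1),
    freq_iqr_lo = c(1, 1, 1, 1, 1, 1),
    freq_iqr_hi = c(6, 5, 2, 32, 8, 2),
    freq_q4     = c(9, 11, 3, 82, 18, 3),
    amp_q2      = c(3.5, 3.7, 6.0, 6.0, 3.6, 4.7),
    amp_iqr_lo  = c(2.6, 2.7, 3.8, 3.7, 2.5, 3.0),
    amp_iqr_hi  = c(5.0, 5.2, 9.2, 9.4, 5.2, 6.5),
    amp_q4      = c(8.5, 9.0, 17.4, 17.0, 9.0, 12.0)
  )
}

#' Build a condition schedule
#'
#' @param conditions A list of condition entries, each a list with fields
#'   `label`, `day_index`, `spike` ([spike_params()]), `rts` ([rts_params()]),
#'   `noise` ([noise_params()]) and `duration_s`.
#' @return A list of class `condition_schedule`.
#' @export
condition_schedule <- function(conditions) {
  if (!is.list(conditions) || length(conditions) == 0) {
    stop_cyanospike("bad_param", "`conditions` must be a non-empty list")
  }
  labels <- vapply(conditions, function(x) x$label, character(1))
  if (anyDuplicated(labels)) {
    stop_cyanospike("duplicate_label",
                    sprintf("duplicate condition label(s): %s",
                            paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  }
  bad <- setdiff(labels, condition_labels())
  if (length(bad)) {
    stop_cyanospike("unknown_condition",
                    sprintf("unknown condition label(s): %s", paste(bad, collapse = ", ")))
  }
  for (x in conditions) {
    stopifnot(inherits(x$spike, "spike_params"), inherits(x$rts, "rts_params"),
              inherits(x$noise, "noise_params"))
    check_number(x$duration_s, "duration_s", min = 0, strict_min = TRUE)
  }
  # keep experimental order
  ord <- order(match(labels, condition_labels()))
  structure(conditions[ord], class = "condition_schedule")
}

#' The default calibrated schedule
#'
#' One recording per condition. Spike rates equal the daily median rates in
#' [schedule_targets()]; amplitude laws are fitted with
#' [calibrate_amplitude()] to the daily amplitude quartiles; the RTS level
#' separation equals the daily amplitude median. RTS switching is sparse
#' (mean inter-excursion interval 200 s, mean high dwell 2 s) on every day,
#' reflecting that the slow fluctuations appear as intermittent seconds-scale
#' excursions.
#'
#' @param duration_s Recording length per condition in seconds (default one
#'   hour).
#' @return A `condition_schedule` with six conditions.
#' @export
default_schedule <- function(duration_s = 3600) {
  tg <- schedule_targets()
  conditions <- lapply(seq_len(nrow(tg)), function(i) {
    cal <- calibrate_amplitude(tg$amp_q2[i], tg$amp_iqr_lo[i],
                               tg$amp_iqr_hi[i], tg$amp_q4[i])
    list(
      label = tg$condition[i],
      day_index = tg$day_index[i],
      spike = spike_params(rate_per_min = tg$freq_q2[i],
                           amp_median_uv = cal$amp_median_uv,
                           amp_spread = cal$amp_spread),
      rts = rts_params(k_up = 0.005, k_down = 0.5, step_uv = tg$amp_q2[i]),
      noise = noise_params(),
      duration_s = duration_s
    )
  })
  condition_schedule(conditions)
}
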