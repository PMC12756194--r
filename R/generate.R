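#' Construct a voltage trace
#'
#' A voltage trace is a tibble with columns `time_s` and `voltage_uV`
#' (microvolts) plus sampling and provenance metadata carried as attributes.
#'
#' @param voltage_uv Numeric vector of voltages in microvolts.
#' @param fs_hz Sampling frequency in Hz (> 0).
#' @param condition Condition label, or `NA`.
#' @param day_index Day index (>= 1), or `NA`.
#' @param seed Generator seed, or `NA` for real data.
#' @return A tibble of class `voltage_trace`.
#' @export
voltage_trace <- function(voltage_uv, fs_hz, condition = NA_character_,
                          day_index = NA_integer_, seed = NA_integer_) {
  check_number(fs_hz, "fs_hz", min = 0, strict_min = TRUE)
  if (!is.numeric(voltage_uv)) {
    stop_cyanospike("bad_param", "`voltage_uv` must be numeric")
  }
  n <- length(voltage_uv)
  out <- new_tibble(
    list(time_s = (seq_len(n) - 1) / fs_hz, voltage_uV = as.numeric(voltage_uv)),
    nrow = n, class = "voltage_trace"
  )
  attr(out, "fs_hz") <- fs_hz
  attr(out, "condition") <- as.character(condition)
  attr(out, "day_index") <- as.integer(day_index)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "units") <- "uV"
  out
}

#' @rdname voltage_trace
#' @param trace A `voltage_trace`.
#' @export
trace_fs <- function(trace) {
  fs <- attr(trace, "fs_hz")
  if (is.null(fs)) {
    stop_cyanospike("bad_param", "`trace` carries no `fs_hz` attribute; build it with voltage_trace() or read_trace()")
  }
  fs
}

#' @rdname voltage_trace
#' @export
trace_duration <- function(trace) nrow(trace) / trace_fs(trace)

empty_events <- function() {
  tibble(onset_s = numeric(), event_class = character(),
         peak_amp_uv = numeric(), duration_s = numeric())
}

# deterministic sub-seed scheme: condition i of a schedule uses
# base = (master + 1009 * i) mod (2^31 - 1), and its spike/RTS/noise
# components use base + 1, base + 2, base + 3.
derive_seed <- function(seed, index, component = 0L) {
  as.integer((as.numeric(seed) + 1009 * index + component) %% 2147483647)
}

#' Generate a random telegraph signal
#'
#' Two-level piecewise-constant signal on levels `{0, step_uv}`, starting in
#' the low state, with exponential dwell times at rate `k_up` in the low
#' state and `k_down` in the high state. Dwell times are floored at one
#' sample.
#'
#' @param duration_s Trace length in seconds (> 0).
#' @param fs_hz Sampling frequency in Hz.
#' @param rts An [rts_params()] object.
#' @param seed Integer seed.
#' @return A list with `signal` (numeric, microvolts), `state` (integer 0/1
#'   per sample) and `events` (tibble, one `rts_step` row per high dwell).
#' @export
generate_rts <- function(duration_s, fs_hz, rts, seed = 1L) {
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(fs_hz, "fs_hz", min = 0, strict_min = TRUE)
  stopifnot(inherits(rts, "rts_params"))
  check_number(rts$k_up, "k_up", min = 0)
  check_number(rts$k_down, "k_down", min = 0)
  n <- round(duration_s * fs_hz)
  if (rts$k_up == 0) {
    # absorbing low state: no excursions ever
    return(list(signal = numeric(n), state = integer(n), events = empty_events()))
  }
  state_runs <- withr::with_seed(seed, {
    lens <- integer(0); vals <- integer(0)
    total <- 0L; cur <- 0L
    while (total < n) {
      rate <- if (cur == 0L) rts$k_up else rts$k_down
      dwell_s <- if (rate > 0) rexp(1, rate) else Inf
      len <- max(1L, if (is.finite(dwell_s)) round(dwell_s * fs_hz) else n)
      len <- min(len, n - total)
      lens <- c(lens, len); vals <- c(vals, cur)
      total <- total + len
      cur <- 1L - cur
    }
    list(lengths = lens, values = vals)
  })
  state <- rep(state_runs$values, state_runs$lengths)
  signal <- state * rts$step_uv
  events <- runs_to_events(state_runs$lengths, state_runs$values, fs_hz,
                           rts$step_uv)
  list(signal = signal, state = state, events = events)
}

runs_to_events <- function(lengths, values, fs_hz, amp) {
  if (!length(lengths) || !any(values == 1L)) return(empty_events())
  starts <- cumsum(c(0L, lengths[-length(lengths)]))
  hi <- values == 1L
  tibble(
    onset_s = starts[hi] / fs_hz,
    event_class = "rts_step",
    peak_amp_uv = rep(amp, sum(hi)),
    duration_s = lengths[hi] / fs_hz
  )
}

#' Generate a fast-spike train
#'
#' Homogeneous Poisson event times at `rate_per_min / 60` per second; each
#' event is rendered as a Gaussian-bell pulse of full width `width_ms`
#' (taken as six standard deviations) whose peak amplitude is log-normal
#' with median `amp_median_uv` and log-sd `amp_spread`. Pulse sign is
#' positive with probability `polarity_prob_pos`; overlapping pulses sum.
#'
#' @param duration_s Trace length in seconds (> 0).
#' @param fs_hz Sampling frequency in Hz; `width_ms` must span at least two
#'   samples.
#' @param spike A [spike_params()] object.
#' @param seed Integer seed.
#' @return A list with `signal` (numeric, microvolts) and `events` (tibble
#'   of ground-truth `fast_spike` rows; `peak_amp_uv` is the unsigned peak).
#' @export
generate_spikes <- function(duration_s, fs_hz, spike, seed = 1L) {
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(fs_hz, "fs_hz", min = 0, strict_min = TRUE)
  stopifnot(inherits(spike, "spike_params"))
  check_number(spike$rate_per_min, "rate_per_min", min = 0)
  width_s <- spike$width_ms / 1000
  if (width_s * fs_hz < 2) {
    stop_cyanospike("bad_param",
                    sprintf("`width_ms` = %g ms spans fewer than 2 samples at fs = %g Hz",
                            spike$width_ms, fs_hz))
  }
  n <- round(duration_s * fs_hz)
  signal <- numeric(n)
  if (spike$rate_per_min == 0) {
    return(list(signal = signal, events = empty_events()))
  }
  ev <- withr::with_seed(seed, {
    n_ev <- rpois(1, spike$rate_per_min / 60 * duration_s)
    t0 <- sort(runif(n_ev, 0, duration_s))
    amp <- rlnorm(n_ev, meanlog = log(spike$amp_median_uv),
                  sdlog = spike$amp_spread)
    sign <- ifelse(runif(n_ev) < spike$polarity_prob_pos, 1, -1)
    list(t0 = t0, amp = amp, sign = sign)
  })
  sd_t <- width_s / 6
  half <- ceiling(3 * sd_t * fs_hz)
  for (i in seq_along(ev$t0)) {
    centre <- ev$t0[i] * fs_hz + 1 # fractional sample index of the peak
    idx <- max(1L, floor(centre - half)):min(n, ceiling(centre + half))
    if (!length(idx)) next
    tt <- (idx - centre) / fs_hz
    signal[idx] <- signal[idx] +
      ev$sign[i] * ev$amp[i] * exp(-tt^2 / (2 * sd_t^2))
  }
  events <- tibble(
    onset_s = pmax(0, ev$t0 - width_s / 2),
    event_class = "fast_spike",
    peak_amp_uv = ev$amp,
    duration_s = width_s
  )
  list(signal = signal, events = events)
}

#' Generate recording noise
#'
#' Sum of white Gaussian noise, a 1/f-shaped Gaussian component (spectrally
#' shaped in the Fourier domain and rescaled to the requested standard
#' deviation) and a deterministic linear drift ramp. All-zero parameters
#' give an identically zero output.
#'
#' @param duration_s Trace length in seconds (> 0).
#' @param fs_hz Sampling frequency in Hz.
#' @param noise A [noise_params()] object.
#' @param seed Integer seed.
#' @return Numeric vector of noise samples in microvolts.
#' @export
generate_noise <- function(duration_s, fs_hz, noise, seed = 1L) {
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(fs_hz, "fs_hz", min = 0, strict_min = TRUE)
  stopifnot(inherits(noise, "noise_params"))
  check_number(noise$white_sd_uv, "white_sd_uv", min = 0)
  check_number(noise$pink_sd_uv, "pink_sd_uv", min = 0)
  n <- round(duration_s * fs_hz)
  out <- numeric(n)
  withr::with_seed(seed, {
    if (noise$white_sd_uv > 0) {
      out <- out + rnorm(n, sd = noise$white_sd_uv)
    }
    if (noise$pink_sd_uv > 0 && n > 2) {
      w <- rnorm(n)
      k <- seq_len(n) - 1
      # symmetric frequency index so the shaped series is real
      fidx <- pmin(k, n - k)
      fidx[1] <- 1
      scale <- 1 / sqrt(fidx)
      scale[1] <- 0
      p <- Re(fft(fft(w) * scale, inverse = TRUE)) / n
      out <- out + p / sd(p) * noise$pink_sd_uv
    }
  })
  if (noise$drift_uv_per_min != 0) {
    t_min <- (seq_len(n) - 1) / fs_hz / 60
    out <- out + noise$drift_uv_per_min * t_min
  }
  out
}

#' Fit a log-normal amplitude law to observed quartiles
#'
#' Returns the log-normal whose median equals `q2` exactly and whose 25th
#' and 75th percentiles fit `(iqr_lo, iqr_hi)` by least squares on the log
#' scale (closed form: `amp_spread = log(iqr_hi / iqr_lo) / (2 qnorm(0.75))`).
#' `q4` is validated as the observed maximum but not fitted.
#'
#' @param q2 Observed median (> 0).
#' @param iqr_lo,iqr_hi Observed 25th and 75th percentiles.
#' @param q4 Observed maximum (>= `iqr_hi`).
#' @return A list with `amp_median_uv`, `amp_spread` and the fitted
#'   quartiles `fitted_q25`, `fitted_q75`.
#' @export
calibrate_amplitude <- function(q2, iqr_lo, iqr_hi, q4) {
  for (nm in c("q2", "iqr_lo", "iqr_hi", "q4")) {
    check_number(get(nm), nm, min = 0, strict_min = TRUE)
  }
  if (!(iqr_lo < q2 && q2 < iqr_hi && iqr_hi <= q4)) {
    stop_cyanospike("bad_quartiles",
                    "quartiles must satisfy iqr_lo < q2 < iqr_hi <= q4")
  }
  z <- qnorm(0.75)
  spread <- log(iqr_hi / iqr_lo) / (2 * z)
  list(amp_median_uv = q2, amp_spread = spread,
       fitted_q25 = q2 * exp(-z * spread),
       fitted_q75 = q2 * exp(z * spread))
}

#' Synthesize all traces of a condition schedule
#'
#' One trace per condition: spikes + RTS + noise, summed sample-wise, each
#' component seeded with a deterministic sub-seed derived from the master
#' seed and the condition index, so every condition is independently
#' reproducible.
#'
#' @param schedule A [condition_schedule()] (default: [default_schedule()]).
#' @param fs_hz Sampling frequency in Hz (default 2000, resolving
#'   millisecond pulses while keeping hour-long traces desk-scale).
#' @param seed Master integer seed.
#' @return A tibble with one row per condition and columns `condition`,
#'   `day_index`, `seed` (the per-condition base seed), and list-columns
#'   `trace` ([voltage_trace()]), `events` (ground-truth event tibble sorted
#'   by onset) and `state` (per-sample RTS state).
#' @export
synthesize_schedule <- function(schedule = default_schedule(), fs_hz = 2000,
                                seed = 1L) {
  stopifnot(inherits(schedule, "condition_schedule"))
  check_number(fs_hz, "fs_hz", min = 0, strict_min = TRUE)
  rows <- lapply(seq_along(schedule), function(i) {
    cond <- schedule[[i]]
    base <- derive_seed(seed, i)
    sp <- generate_spikes(cond$duration_s, fs_hz, cond$spike,
                          seed = derive_seed(seed, i, 1L))
    rt <- generate_rts(cond$duration_s, fs_hz, cond$rts,
                       seed = derive_seed(seed, i, 2L))
    no <- generate_noise(cond$duration_s, fs_hz, cond$noise,
                         seed = derive_seed(seed, i, 3L))
    trace <- voltage_trace(sp$signal + rt$signal + no, fs_hz,
                           condition = cond$label, day_index = cond$day_index,
                           seed = base)
    events <- arrange(bind_rows(sp$events, rt$events), .data$onset_s)
    tibble(condition = cond$label, day_index = cond$day_index, seed = base,
           trace = list(trace), events = list(events), state = list(rt$state))
  })
  list_rbind(rows)
}
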