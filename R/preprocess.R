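#' Remove the slow baseline with a running median
#'
#' Estimates the baseline as a running median over `window_s` and subtracts
#' it, leaving a zero-median trace. The window must be much longer than the
#' RTS dwell scale (default 60 s vs seconds-scale dwells) so telegraph steps
#' are not absorbed: as long as the high state occupies less than half of
#' any window, the windowed median tracks the low level and step amplitudes
#' survive. For speed the median is computed on short-block medians
#' (window/120 per block) and interpolated back to the full sample grid;
#' block medians are transparent to both the drift and the step structure.
#'
#' @param trace A [voltage_trace()].
#' @param window_s Running-median window in seconds (>= 3 samples).
#' @return The trace with `voltage_uV` detrended and a new `baseline_uV`
#'   column such that input = `voltage_uV + baseline_uV` exactly.
#' @export
remove_baseline <- function(trace, window_s = 60) {
  fs <- trace_fs(trace)
  check_number(window_s, "window_s", min = 0, strict_min = TRUE)
  n <- nrow(trace)
  if (window_s * fs < 3) {
    stop_cyanospike("bad_param",
                    sprintf("`window_s` = %g s spans fewer than 3 samples at fs = %g Hz",
                            window_s, fs))
  }
  v <- trace$voltage_uV
  block <- max(1L, round(window_s * fs / 120))
  nb <- ceiling(n / block)
  if (nb >= 3) {
    pad <- nb * block - n
    vb <- matrix(c(v, rep(v[n], pad)), nrow = block)
    bm <- col_medians(vb)
    k <- min(nb, round(window_s * fs / block))
    k <- max(3L, as.integer(k + (k %% 2 == 0))) # odd, >= 3
    if (k > nb) k <- as.integer(nb - ((nb + 1) %% 2))
    sm <- stats::runmed(bm, k, endrule = "median")
    # the windowed median of a near-balanced two-level mixture can flip
    # between the levels as the window slides; a same-window moving average
    # suppresses that switching artifact while leaving ramps and offsets
    # untouched
    sm <- ma_centered(sm, k)
    centres <- (seq_len(nb) - 0.5) * block
    baseline <- approx(centres, sm, xout = seq_len(n), rule = 2)$y
  } else {
    baseline <- rep(median(v), n)
  }
  detrended <- v - baseline
  shift <- median(detrended)
  detrended <- detrended - shift
  baseline <- baseline + shift
  out <- trace
  out$voltage_uV <- detrended
  out$baseline_uV <- baseline
  out
}

col_medians <- function(m) {
  apply(m, 2, median)
}

# centred moving average with shrinking symmetric windows at the edges
# Zero-phase (forward-backward) IIR filtering with odd-reflection padding so
# start-up transients die out before the retained segment.
zero_phase_filter <- function(x, b, a, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- if (pad > 0) {
    c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  } else {
    x
  }
  y <- iir_filter_cpp(b, a, xp)
  y <- rev(iir_filter_cpp(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

ma_centered <- function(x, k) {
  n <- length(x)
  h <- min((k - 1L) %/% 2L, n - 1L)
  cs <- cumsum(c(0, x))
  idx <- seq_len(n)
  lo <- pmax(1L, idx - h)
  hi <- pmin(n, idx + h)
  half <- pmin(idx - lo, hi - idx) # keep windows symmetric near the edges
  lo <- idx - half
  hi <- idx + half
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Split a trace into fast and slow bands
#'
#' Zero-phase (forward-backward, 4th-order Butterworth) high-pass gives the
#' fast band; the slow band is the exact complement, so
#' `fast_uV + slow_uV == voltage_uV` sample-wise. The default corner of
#' 10 Hz sits two octaves from both event classes: millisecond pulses pass
#' to the fast band nearly unattenuated while seconds-scale telegraph
#' plateaus stay in the slow band.
#'
#' @param trace A [voltage_trace()] (ideally baseline-removed first).
#' @param fc_hz Corner frequency, 0 < fc < fs/2.
#' @return The trace with added columns `fast_uV` and `slow_uV`.
#' @export
split_bands <- function(trace, fc_hz = 10) {
  fs <- trace_fs(trace)
  check_number(fc_hz, "fc_hz", min = 0, max = fs / 2,
               strict_min = TRUE, strict_max = TRUE)
  v <- trace$voltage_uV
  if (all(v == 0)) {
    fast <- numeric(length(v))
  } else {
    bf <- signal::butter(4, fc_hz / (fs / 2), type = "high")
    fast <- zero_phase_filter(v, bf$b, bf$a, pad = ceiling(3 * fs / fc_hz))
  }
  out <- trace
  out$fast_uV <- fast
  out$slow_uV <- v - fast
  attr(out, "fc_hz") <- fc_hz
  out
}

#' Robust noise scale of the fast band
#'
#' `1.4826 x` the median absolute deviation from the median: consistent for
#' the standard deviation under Gaussian noise and nearly unaffected by a
#' small fraction of large spikes. Invariant to constant offsets.
#'
#' @param x A numeric vector, or a trace tibble (uses `fast_uV` if present,
#'   else `voltage_uV`).
#' @return Noise standard-deviation estimate in microvolts.
#' @export
noise_sigma <- function(x) {
  if (is.data.frame(x)) {
    x <- if ("fast_uV" %in% names(x)) x$fast_uV else x$voltage_uV
  }
  if (length(x) < 1000) {
    stop_cyanospike("bad_param",
                    "noise_sigma() needs at least 1000 samples for a stable estimate")
  }
  mad(x)
}
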