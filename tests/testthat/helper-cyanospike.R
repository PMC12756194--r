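# Shared fixtures and oracles, built in code at test time.

# Noise-free trace of Gaussian-bell pulses at given peak times/amplitudes.
pulse_trace <- function(peak_times, amps, fs = 2000, duration = NULL,
                        width_ms = 5) {
  duration <- duration %||% (max(peak_times) + 1)
  n <- round(duration * fs)
  v <- numeric(n)
  sd_t <- width_ms / 1000 / 6
  t <- (seq_len(n) - 1) / fs
  for (i in seq_along(peak_times)) {
    v <- v + amps[i] * exp(-(t - peak_times[i])^2 / (2 * sd_t^2))
  }
  voltage_trace(v, fs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force spike detector: scans every sample against the
# threshold and merges by the same refractory rule, one step at a time.
brute_force_detect <- function(v, fs, sigma, k_sigma = 5, refractory_ms = 20) {
  thr <- k_sigma * sigma
  refr <- refractory_ms / 1000 * fs
  runs <- list()
  in_run <- FALSE
  for (i in seq_along(v)) {
    if (abs(v[i]) > thr) {
      if (!in_run) {
        runs[[length(runs) + 1]] <- c(start = i, end = i)
        in_run <- TRUE
      } else {
        runs[[length(runs)]]["end"] <- i
      }
    } else {
      in_run <- FALSE
    }
  }
  if (!length(runs)) {
    return(data.frame(onset_s = numeric(), peak_amp_uv = numeric(),
                      duration_s = numeric()))
  }
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    prev <- merged[[length(merged)]]
    if (r["start"] - prev["end"] - 1 < refr) {
      merged[[length(merged)]]["end"] <- r["end"]
    } else {
      merged[[length(merged) + 1]] <- r
    }
  }
  rows <- lapply(merged, function(r) {
    idx <- r["start"]:r["end"]
    data.frame(onset_s = (r[["start"]] - 1) / fs,
               peak_amp_uv = max(abs(v[idx])),
               duration_s = (r[["end"]] - r[["start"]] + 1) / fs)
  })
  do.call(rbind, rows)
}

# Sort-based quantile oracle (linear interpolation between order statistics).
brute_force_quartiles <- function(x) {
  s <- sort(x)
  n <- length(s)
  interp <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  c(q25 = interp(0.25), q50 = interp(0.5), q75 = interp(0.75), max = s[n])
}

# Greedy onset matching of detected vs true events within a tolerance;
# returns counts for precision/recall.
match_events <- function(detected, truth, tol_s = 0.02) {
  used <- rep(FALSE, nrow(detected))
  tp <- 0L
  d_mid <- detected$onset_s + detected$duration_s / 2
  t_mid <- truth$onset_s + truth$duration_s / 2
  for (k in seq_len(nrow(truth))) {
    j <- which(!used & abs(d_mid - t_mid[k]) < tol_s)
    if (length(j)) {
      used[j[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = nrow(detected) - tp, fn = nrow(truth) - tp)
}

f1_score <- function(m) {
  prec <- m$tp / max(1L, m$tp + m$fp)
  rec <- m$tp / max(1L, m$tp + m$fn)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}
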