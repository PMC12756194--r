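#' Detect fast spikes by robust thresholding
#'
#' Marks samples where `|v|` exceeds `k_sigma * sigma` on the fast band,
#' merges supra-threshold excursions separated by less than `refractory_ms`,
#' and emits one event per merged excursion: onset at the first
#' supra-threshold sample, duration the supra-threshold extent, amplitude
#' the maximum absolute excursion. Detection is polarity-agnostic.
#'
#' @param trace A trace tibble; uses `fast_uV` if present (output of
#'   [split_bands()]), else `voltage_uV`.
#' @param sigma Noise scale in microvolts (> 0), typically [noise_sigma()].
#' @param config A [detection_config()].
#' @return Event tibble (`onset_s`, `event_class = "fast_spike"`,
#'   `peak_amp_uv`, `duration_s`, plus `peak_s`, the time of the absolute
#'   peak), sorted by onset. Empty trace gives an empty tibble.
#' @export
detect_spikes <- function(trace, sigma, config = detection_config()) {
  check_number(sigma, "sigma", min = 0, strict_min = TRUE)
  fs <- trace_fs(trace)
  v <- if ("fast_uV" %in% names(trace)) trace$fast_uV else trace$voltage_uV
  if (length(v) == 0) return(add_peak_col(empty_events()))
  if (any(!is.finite(v))) {
    stop_cyanospike("nonfinite", "trace contains non-finite samples")
  }
  thr <- config$k_sigma * sigma
  supra <- abs(v) > thr
  if (!any(supra)) return(add_peak_col(empty_events()))
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # merge excursions whose gap is shorter than the refractory period
  refractory_samples <- config$refractory_ms / 1000 * fs
  if (nrow(runs) > 1) {
    gaps <- runs[-1, 1] - runs[-nrow(runs), 2] - 1L
    new_event <- c(TRUE, gaps >= refractory_samples)
    grp <- cumsum(new_event)
    runs <- cbind(tapply(runs[, 1], grp, min), tapply(runs[, 2], grp, max))
    dimnames(runs) <- NULL
  }
  out <- lapply(seq_len(nrow(runs)), function(i) {
    idx <- runs[i, 1]:runs[i, 2]
    pk <- idx[which.max(abs(v[idx]))]
    c(onset = (runs[i, 1] - 1) / fs,
      dur = (runs[i, 2] - runs[i, 1] + 1) / fs,
      amp = abs(v[pk]), peak = (pk - 1) / fs)
  })
  out <- do.call(rbind, out)
  tibble(onset_s = out[, "onset"], event_class = "fast_spike",
         peak_amp_uv = out[, "amp"], duration_s = out[, "dur"],
         peak_s = out[, "peak"])
}

add_peak_col <- function(events) {
  events$peak_s <- events$onset_s + events$duration_s / 2
  events
}

#' Segment RTS states in the slow band
#'
#' Fits a two-level model to the slow-band samples: an equal-variance
#' two-component Gaussian mixture (fitted on an even subsample, hard
#' assignment of every sample at the posterior boundary), then enforces the
#' minimum dwell by merging shorter runs into their longer neighbour (ties
#' merge backward in time). One `rts_step` event is emitted per high-state
#' dwell, with amplitude equal to the re-estimated level separation.
#'
#' Segmentation is declared degenerate ("no RTS detected", not an error)
#' when BIC prefers a single component over two, or when the fitted level
#' separation is below twice the within-level sigma.
#'
#' @param trace A trace tibble; uses `slow_uV` if present (output of
#'   [split_bands()]), else `voltage_uV`. Duration must be at least
#'   `10 * min_dwell_s`.
#' @param config A [detection_config()].
#' @param max_fit_samples Subsample cap for the mixture fit.
#' @return An object of class `rts_segmentation`: a list with `state`
#'   (integer 0/1 per sample), `events` (tibble of `rts_step` rows),
#'   `levels` (fitted low/high means), `step_uv` (re-estimated separation),
#'   `sigma_within`, `no_rts` (logical flag) and `fs_hz`. Supports
#'   [tidy()] and [glance()].
#' @export
segment_rts <- function(trace, config = detection_config(),
                        max_fit_samples = 20000) {
  fs <- trace_fs(trace)
  v <- if ("slow_uV" %in% names(trace)) trace$slow_uV else trace$voltage_uV
  n <- length(v)
  if (n / fs < 10 * config$min_dwell_s) {
    stop_cyanospike("bad_param",
                    sprintf("trace duration %.3g s is below 10 x min_dwell_s = %.3g s",
                            n / fs, 10 * config$min_dwell_s))
  }
  empty <- function() {
    new_rts_segmentation(state = integer(n), events = empty_events(),
                         levels = c(NA_real_, NA_real_), step_uv = NA_real_,
                         sigma_within = NA_real_, no_rts = TRUE, fs_hz = fs)
  }
  # fit on a decimated subsample: the slow band carries no information above
  # fc_hz, and (near-)independent points keep the BIC comparison honest
  by <- max(1L, round(fs / (2 * config$fc_hz)), ceiling(n / max_fit_samples))
  xs <- v[seq(1L, n, by = by)]
  fit <- fit_two_levels(xs)
  if (is.null(fit) || !fit$two_components ||
      fit$sep < 2 * fit$sigma_within) {
    return(empty())
  }
  # equal-variance posterior decision boundary between the two levels
  bound <- (fit$mu[1] + fit$mu[2]) / 2 +
    if (fit$sigma_within > 0) {
      fit$sigma_within^2 * log(fit$pro[1] / fit$pro[2]) / fit$sep
    } else 0
  state <- as.integer(v > bound)
  raw_r <- rle(state)
  raw_transitions <- cumsum(raw_r$lengths[-length(raw_r$lengths)]) / fs
  state <- enforce_min_dwell(state, round(config$min_dwell_s * fs))
  if (!any(state == 1L) || all(state == 1L)) return(empty())
  r <- rle(state)
  step <- mean(v[state == 1L]) - mean(v[state == 0L])
  events <- runs_to_events(r$lengths, r$values, fs, step)
  seg <- new_rts_segmentation(state = state, events = events,
                              levels = fit$mu, step_uv = step,
                              sigma_within = fit$sigma_within, no_rts = FALSE,
                              fs_hz = fs)
  # pre-merge transition times: even a sub-resolution dwell leaves a pair of
  # step-edge artifacts in the fast band, so the classifier needs them all
  seg$raw_transitions_s <- raw_transitions
  seg
}

# Equal-variance univariate Gaussian mixture, one vs two components by BIC.
# The two-component EM is initialised from a deterministic two-means
# partition seeded at the value-range extremes: a sparse high state (a few
# percent occupancy) is a far outlier component that default mixture
# initialisations tend to miss, whereas the extreme-seeded split hands it to
# the EM directly. Degenerate EM (zero within-level variance, e.g. a
# noise-free telegraph signal) falls back to the two-means solution itself.
fit_two_levels <- function(xs) {
  if (length(unique(xs)) < 2) return(NULL)
  n <- length(xs)
  init <- two_means_1d(xs)
  em <- tryCatch(
    suppressWarnings(meE(data = xs, z = cbind(1 - init$assign, init$assign))),
    error = function(e) NULL
  )
  if (!is.null(em) && is.finite(em$loglik %||% NA_real_) &&
      all(is.finite(em$parameters$mean))) {
    # E,2 has 4 free parameters (2 means, 1 variance, 1 weight); E,1 has 2
    bic2 <- 2 * em$loglik - 4 * log(n)
    sd1 <- sqrt(mean((xs - mean(xs))^2))
    bic1 <- 2 * sum(dnorm(xs, mean(xs), sd1, log = TRUE)) - 2 * log(n)
    if (bic2 <= bic1) return(list(two_components = FALSE))
    ord <- order(as.numeric(em$parameters$mean))
    mu <- as.numeric(em$parameters$mean)[ord]
    pro <- as.numeric(em$parameters$pro)[ord]
    sig <- sqrt(em$parameters$variance$sigmasq[1])
    return(list(two_components = TRUE, mu = mu, pro = pro,
                sigma_within = sig, sep = diff(mu)))
  }
  # degenerate EM: use the two-means partition directly
  mu <- init$mu
  pro <- c(1 - mean(init$assign), mean(init$assign))
  sig <- sqrt((sum((xs[init$assign == 0] - mu[1])^2) +
                 sum((xs[init$assign == 1] - mu[2])^2)) / max(1, n - 2))
  list(two_components = TRUE, mu = mu, pro = pro, sigma_within = sig,
       sep = diff(mu))
}

# Deterministic 1-D two-means: centres start at the data extremes,
# assignment by midpoint threshold, Lloyd iterations to convergence.
two_means_1d <- function(xs, max_iter = 50) {
  mu <- range(xs)
  assign <- NULL
  for (i in seq_len(max_iter)) {
    new_assign <- as.integer(xs > (mu[1] + mu[2]) / 2)
    if (identical(new_assign, assign)) break
    assign <- new_assign
    m0 <- if (any(assign == 0L)) mean(xs[assign == 0L]) else mu[1]
    m1 <- if (any(assign == 1L)) mean(xs[assign == 1L]) else mu[2]
    mu <- c(m0, m1)
  }
  list(mu = mu, assign = assign)
}

# Merge runs shorter than min_samples into their longer neighbour; the
# shortest run goes first (ties: earliest), and a tie between neighbours
# merges backward in time. Deterministic.
enforce_min_dwell <- function(state, min_samples) {
  if (min_samples <= 1L) return(state)
  r <- rle(state)
  lens <- r$lengths
  vals <- r$values
  while (length(lens) > 1 && min(lens) < min_samples) {
    i <- which.min(lens)
    into <- if (i == 1L) {
      2L
    } else if (i == length(lens)) {
      i - 1L
    } else if (lens[i + 1L] > lens[i - 1L]) {
      i + 1L
    } else {
      i - 1L # longer backward neighbour, or tie -> backward
    }
    vals[i] <- vals[into]
    # coalesce equal-valued adjacent runs
    keep <- c(TRUE, vals[-1] != vals[-length(vals)])
    grp <- cumsum(keep)
    lens <- as.integer(tapply(lens, grp, sum))
    vals <- as.integer(tapply(vals, grp, function(x) x[1]))
  }
  rep(vals, lens)
}

new_rts_segmentation <- function(state, events, levels, step_uv,
                                 sigma_within, no_rts, fs_hz) {
  structure(list(state = state, events = events, levels = levels,
                 step_uv = step_uv, sigma_within = sigma_within,
                 no_rts = no_rts, fs_hz = fs_hz),
            class = "rts_segmentation")
}

#' @export
print.rts_segmentation <- function(x, ...) {
  if (x$no_rts) {
    cat("<rts_segmentation> no RTS detected\n")
  } else {
    cat(sprintf("<rts_segmentation> %d high dwell(s), step %.2f uV, within-sigma %.3f uV\n",
                nrow(x$events), x$step_uv, x$sigma_within))
  }
  invisible(x)
}

#' @rdname segment_rts
#' @param x An `rts_segmentation`.
#' @param ... Unused.
#' @export
tidy.rts_segmentation <- function(x, ...) {
  x$events
}

#' @rdname segment_rts
#' @export
glance.rts_segmentation <- function(x, ...) {
  tibble(n_dwells = nrow(x$events), step_uv = x$step_uv,
         level_lo = x$levels[1], level_hi = x$levels[2],
         sigma_within = x$sigma_within, no_rts = x$no_rts,
         high_fraction = mean(x$state == 1L))
}

#' Merge spike and RTS events into one classified list
#'
#' Takes the union of both sorted lists in chronological order. Two
#' adjustments resolve class ambiguity at the fast/slow boundary:
#' fast-band events whose peak falls within `edge_guard_s` of a segmented
#' state transition are step edge artifacts of the band-split filter and
#' are absorbed into the corresponding `rts_step` event (dropped from the
#' spike list); any remaining fast-band event with duration at or above
#' `class_boundary_s` is reclassified `rts_step` if it lies inside a
#' segmented high dwell, otherwise kept as `fast_spike`.
#'
#' @param spike_events Sorted event tibble from [detect_spikes()].
#' @param rts_events Sorted event tibble from [segment_rts()] (its
#'   `$events`), or an `rts_segmentation` (preferred: it carries the
#'   pre-merge transition times, so edge artifacts of sub-resolution dwells
#'   are also recognised).
#' @param config A [detection_config()].
#' @return A single sorted event tibble.
#' @export
merge_and_classify <- function(spike_events, rts_events,
                               config = detection_config()) {
  transitions <- NULL
  if (inherits(rts_events, "rts_segmentation")) {
    transitions <- rts_events$raw_transitions_s
    rts_events <- rts_events$events
  }
  for (ev in list(spike_events, rts_events)) {
    if (nrow(ev) > 1 && is.unsorted(ev$onset_s)) {
      stop_cyanospike("unsorted_events", "event lists must be sorted by `onset_s`")
    }
  }
  sp <- as_tibble(spike_events)
  if (is.null(transitions)) {
    transitions <- sort(c(rts_events$onset_s,
                          rts_events$onset_s + rts_events$duration_s))
  }
  if (nrow(sp) > 0 && length(transitions) > 0) {
    peaks <- if ("peak_s" %in% names(sp)) sp$peak_s else sp$onset_s + sp$duration_s / 2
    near_edge <- vapply(peaks, function(p) {
      min(abs(transitions - p)) <= config$edge_guard_s
    }, logical(1))
    sp <- sp[!near_edge, , drop = FALSE]
    peaks <- peaks[!near_edge]
    long <- sp$duration_s >= config$class_boundary_s
    if (any(long)) {
      in_dwell <- vapply(which(long), function(i) {
        any(peaks[i] >= rts_events$onset_s &
              peaks[i] <= rts_events$onset_s + rts_events$duration_s)
      }, logical(1))
      sp$event_class[which(long)[in_dwell]] <- "rts_step"
    }
  }
  sp$peak_s <- NULL
  out <- bind_rows(sp, as_tibble(rts_events))
  arrange(out, .data$onset_s)
}
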