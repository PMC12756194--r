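test_that("absorbing RTS low state yields a constant zero trace", {
  r <- generate_rts(100, 200, rts_params(k_up = 0, k_down = 0.5, step_uv = 6),
                    seed = 1)
  expect_identical(r$signal, numeric(100 * 200))
  expect_identical(unique(r$state), 0L)
  expect_identical(nrow(r$events), 0L)
})

test_that("RTS dwell times follow the exponential closed form 1/k", {
  # modest sampling rate: dwell scale (seconds) >> sample period
  fs <- 100
  high <- numeric(0)
  low_count <- 0
  low_sum <- 0
  for (s in 1:40) {
    r <- generate_rts(2000, fs, rts_params(0.5, 0.5, 6), seed = 1000 + s)
    high <- c(high, r$events$duration_s)
    runs <- rle(r$state)
    low_runs <- runs$lengths[runs$values == 0L]
    # interior low dwells only (first/last are censored by the trace edges)
    if (length(low_runs) > 2) {
      low_sum <- low_sum + sum(low_runs[2:(length(low_runs) - 1)]) / fs
      low_count <- low_count + length(low_runs) - 2
    }
  }
  expect_gt(length(high), 500)
  expect_lt(abs(mean(high) / 2.0 - 1), 0.1)
  expect_lt(abs((low_sum / low_count) / 2.0 - 1), 0.1)
})

test_that("zero spike rate produces an empty train", {
  s <- generate_spikes(600, 400, spike_params(rate_per_min = 0), seed = 3)
  expect_identical(s$signal, numeric(600 * 400))
  expect_identical(nrow(s$events), 0L)
})

test_that("spike counts are Poisson with the requested mean and dispersion", {
  counts <- vapply(1:200, function(s) {
    nrow(generate_spikes(3600, 400, spike_params(rate_per_min = 5),
                         seed = 2000 + s)$events)
  }, numeric(1))
  expect_lt(abs(mean(counts) / 300 - 1), 0.05)
  disp <- var(counts) / mean(counts)
  expect_gt(disp, 0.8)
  expect_lt(disp, 1.2)
})

test_that("spike rendering matches the requested width and amplitude", {
  fs <- 2000
  s <- generate_spikes(60, fs, spike_params(rate_per_min = 60, amp_spread = 0,
                                            amp_median_uv = 8,
                                            polarity_prob_pos = 1),
                       seed = 11)
  # peaks fall between samples, so the sampled maximum sits just under the
  # rendered amplitude
  expect_lt(max(s$signal), 8 + 1e-9)
  expect_gt(max(s$signal), 8 * 0.995)
  expect_true(all(s$events$duration_s == 0.005))
  # width must resolve to >= 2 samples
  expect_error(generate_spikes(10, 300, spike_params(width_ms = 5)),
               class = "cyanospike_error_bad_param")
})

test_that("noise generator is zero when asked and Gaussian when not", {
  z <- generate_noise(10, 100, noise_params(0, 0, 0), seed = 5)
  expect_identical(z, numeric(1000))
  w <- generate_noise(1000, 1000, noise_params(1, 0, 0), seed = 6)
  expect_lt(abs(sd(w) - 1), 0.01)
  # drift is deterministic: 2 uV/min over 2 min ends at 4 uV
  d <- generate_noise(120, 100, noise_params(0, 0, 2), seed = 7)
  expect_equal(d[length(d)], 2 * (120 - 1 / 100) / 60, tolerance = 1e-10)
})

test_that("pink noise has a 1/f power spectrum", {
  fs <- 100
  p <- generate_noise(2000, fs, noise_params(0, 1, 0), seed = 8)
  pxx <- Mod(fft(p)[2:(length(p) / 2)])^2
  f <- (seq_along(pxx)) * fs / length(p)
  keep <- f >= 0.01 & f <= 10
  # log-binned periodogram regression
  bins <- cut(log10(f[keep]), 24)
  lp <- tapply(log10(pxx[keep]), bins, mean)
  lf <- tapply(log10(f[keep]), bins, mean)
  slope <- coef(lm(lp ~ lf))[2]
  expect_lt(abs(slope - (-1)), 0.2)
})

test_that("amplitude calibration hits the observed quartiles", {
  cal <- calibrate_amplitude(3.5, 2.6, 5.0, 8.5)
  expect_identical(cal$amp_median_uv, 3.5)
  expect_lt(abs(cal$fitted_q25 / 2.6 - 1), 0.1)
  expect_lt(abs(cal$fitted_q75 / 5.0 - 1), 0.1)
  # Monte-Carlo round trip
  x <- withr::with_seed(9, rlnorm(1e5, log(cal$amp_median_uv), cal$amp_spread))
  q <- quantile(x, c(0.25, 0.5, 0.75))
  expect_lt(max(abs(q / c(2.6, 3.5, 5.0) - 1)), 0.05)
  # near-degenerate IQR collapses the spread
  expect_lt(calibrate_amplitude(3.5, 3.4999, 3.5001, 8.5)$amp_spread, 1e-4)
  expect_error(calibrate_amplitude(3.5, 5.0, 2.6, 8.5),
               class = "cyanospike_error_bad_quartiles")
})

test_that("schedule synthesis is additive, deterministic and calibrated", {
  sch <- default_schedule(120)
  sim1 <- synthesize_schedule(sch, fs_hz = 500, seed = 42)
  sim2 <- synthesize_schedule(sch, fs_hz = 500, seed = 42)
  expect_identical(sim1$trace[[3]]$voltage_uV, sim2$trace[[3]]$voltage_uV)
  expect_identical(sim1$events[[3]], sim2$events[[3]])

  # trace = spikes + RTS + noise exactly, using the documented sub-seeds
  i <- 4
  cond <- sch[[i]]
  sp <- generate_spikes(120, 500, cond$spike,
                        seed = cyanospike:::derive_seed(42, i, 1L))
  rt <- generate_rts(120, 500, cond$rts,
                     seed = cyanospike:::derive_seed(42, i, 2L))
  no <- generate_noise(120, 500, cond$noise,
                       seed = cyanospike:::derive_seed(42, i, 3L))
  expect_identical(sim1$trace[[i]]$voltage_uV, sp$signal + rt$signal + no)

  # day 4 carries the largest true spike rate
  rates <- vapply(sch, function(x) x$spike$rate_per_min, numeric(1))
  expect_identical(which.max(rates), 4L)
  counts <- vapply(sim1$events, function(e) sum(e$event_class == "fast_spike"),
                   numeric(1))
  expect_identical(which.max(counts), 4L)

  # duplicate labels rejected
  expect_error(condition_schedule(list(sch[[1]], sch[[1]])),
               class = "cyanospike_error_duplicate_label")
})

test_that("an all-zero schedule produces silent traces with empty truth", {
  quiet <- list(label = "-Nd1", day_index = 1L,
                spike = spike_params(rate_per_min = 0),
                rts = rts_params(k_up = 0),
                noise = noise_params(0, 0, 0), duration_s = 30)
  sim <- synthesize_schedule(condition_schedule(list(quiet)), fs_hz = 500,
                             seed = 1)
  expect_identical(sim$trace[[1]]$voltage_uV, numeric(15000))
  expect_identical(nrow(sim$events[[1]]), 0L)
})

test_that("default schedule parameters carry the reported daily medians", {
  sch <- default_schedule()
  expect_identical(vapply(sch, function(x) x$spike$rate_per_min, numeric(1)),
                   c(1, 2, 1, 5, 3, 1))
  expect_identical(sch[[1]]$spike$amp_median_uv, 3.5)
  expect_identical(sch[[3]]$rts$step_uv, 6.0)
})
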