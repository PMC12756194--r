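test_that("noise-free pulse trains are recovered exactly", {
  fs <- 2000
  peaks <- c(1, 3.5, 7, 12, 20, 33, 41)
  tr <- pulse_trace(peaks, rep(20, 7), fs = fs, duration = 45)
  ev <- detect_spikes(tr, sigma = 1)
  expect_identical(nrow(ev), 7L)
  expect_true(all(abs(ev$peak_amp_uv - 20) < 0.5))
  expect_true(all(abs(ev$onset_s + ev$duration_s / 2 - peaks) < 0.005))
  expect_true(all(ev$duration_s < 0.1))
  # amplitude fidelity well under 3%
  expect_lt(max(abs(ev$peak_amp_uv / 20 - 1)), 0.03)
})

test_that("detection matches a brute-force scan exactly on small traces", {
  fs <- 1000
  for (s in 1:10) {
    v <- withr::with_seed(300 + s, {
      x <- rnorm(8000)
      k <- sample(10:40, 1)
      pos <- sample(100:7900, k)
      for (p in pos) x[p:(p + 4)] <- x[p:(p + 4)] + runif(1, 4, 30)
      x
    })
    tr <- voltage_trace(v, fs)
    got <- detect_spikes(tr, sigma = 1)
    want <- brute_force_detect(v, fs, sigma = 1)
    expect_identical(nrow(got), nrow(want))
    expect_equal(got$onset_s, want$onset_s)
    expect_equal(got$peak_amp_uv, want$peak_amp_uv)
    expect_equal(got$duration_s, want$duration_s)
  }
})

test_that("raising the threshold never creates events", {
  fs <- 2000
  sim <- synthesize_schedule(default_schedule(120), fs_hz = fs, seed = 17)
  pre <- split_bands(remove_baseline(sim$trace[[4]], 60), 10)
  sigma <- noise_sigma(pre)
  counts <- vapply(c(4, 5, 6, 8, 10), function(k) {
    nrow(detect_spikes(pre, sigma, detection_config(k_sigma = k)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("non-finite samples are rejected, empty traces give empty lists", {
  tr <- voltage_trace(c(rnorm(100), NA, rnorm(100)), 100)
  expect_error(detect_spikes(tr, 1), class = "cyanospike_error_nonfinite")
  expect_identical(nrow(detect_spikes(voltage_trace(numeric(0), 100), 1)), 0L)
})

test_that("noise-free telegraph states are segmented to the sample", {
  fs <- 500
  dwells <- rep(c(4, 2), 12)  # 12 high dwells of 2 s separated by 4 s lows
  state <- rep(rep(c(0L, 1L), 12), times = round(dwells * fs))
  tr <- voltage_trace(state * 6, fs)
  seg <- segment_rts(tr)
  expect_false(seg$no_rts)
  expect_identical(nrow(seg$events), 12L)
  expect_identical(seg$state, state)
  expect_equal(seg$step_uv, 6)
  truth_onsets <- cumsum(rep(c(4, 2), 12))[seq(1, 23, by = 2)]
  expect_true(all(abs(seg$events$onset_s - truth_onsets) <= 1 / fs))
})

test_that("noisy telegraph dwells are recovered with small duration error", {
  fs <- 500
  for (s in 1:3) {
    r <- generate_rts(400, fs, rts_params(0.5, 0.5, 6), seed = 400 + s)
    v <- r$signal + generate_noise(400, fs, noise_params(1, 0, 0),
                                   seed = 500 + s)
    seg <- segment_rts(voltage_trace(v, fs))
    expect_false(seg$no_rts)
    expect_lt(abs(seg$step_uv / 6 - 1), 0.15)
    # resolvable dwells: the dwell and both flanking dwells exceed min_dwell
    runs <- rle(r$state)
    lens <- runs$lengths / fs
    ok <- which(runs$values == 1L & lens >= 0.5)
    ok <- ok[vapply(ok, function(i) {
      (i == 1 || lens[i - 1] >= 0.5) &&
        (i == length(lens) || lens[i + 1] >= 0.5)
    }, logical(1))]
    starts <- (cumsum(c(0, runs$lengths))[ok]) / fs
    durs <- lens[ok]
    matched <- vapply(seq_along(ok), function(j) {
      hit <- which(abs(seg$events$onset_s - starts[j]) < 0.25)
      length(hit) > 0 &&
        abs(seg$events$duration_s[hit[1]] - durs[j]) / durs[j] < 0.1
    }, logical(1))
    expect_gt(mean(matched), 0.9)
  }
})

test_that("featureless traces are flagged as having no RTS", {
  fs <- 500
  v <- withr::with_seed(21, rnorm(fs * 120))
  seg <- segment_rts(voltage_trace(v, fs))
  expect_true(seg$no_rts)
  expect_identical(nrow(seg$events), 0L)
  expect_identical(unique(seg$state), 0L)
  g <- glance(seg)
  expect_true(g$no_rts)
  expect_identical(g$n_dwells, 0L)
})

test_that("tidy and glance expose the segmentation results", {
  fs <- 500
  r <- generate_rts(200, fs, rts_params(0.5, 0.5, 6), seed = 31)
  v <- r$signal + generate_noise(200, fs, noise_params(0.5, 0, 0), seed = 32)
  seg <- segment_rts(voltage_trace(v, fs))
  expect_identical(tidy(seg), seg$events)
  expect_identical(glance(seg)$n_dwells, nrow(seg$events))
})

test_that("merge_and_classify unions, guards edges and keeps order", {
  cfg <- detection_config()
  sp <- tibble::tibble(onset_s = c(1, 7), event_class = "fast_spike",
                       peak_amp_uv = c(10, 12), duration_s = 0.005)
  rts <- tibble::tibble(onset_s = 3, event_class = "rts_step",
                        peak_amp_uv = 6, duration_s = 2)
  out <- merge_and_classify(sp, rts, cfg)
  expect_identical(out$onset_s, c(1, 3, 7))
  expect_identical(out$event_class, c("fast_spike", "rts_step", "fast_spike"))

  # a short spike inside a high dwell keeps its class (distinct time scale)
  sp_in <- tibble::tibble(onset_s = 4, event_class = "fast_spike",
                          peak_amp_uv = 9, duration_s = 0.005)
  out2 <- merge_and_classify(sp_in, rts, cfg)
  expect_identical(out2$event_class[out2$onset_s == 4], "fast_spike")

  # a fast-band event right at a transition is absorbed as a step artifact
  sp_edge <- tibble::tibble(onset_s = c(2.98, 10), event_class = "fast_spike",
                            peak_amp_uv = c(3, 8), duration_s = 0.02)
  out3 <- merge_and_classify(sp_edge, rts, cfg)
  expect_identical(sum(out3$event_class == "fast_spike"), 1L)

  # a long fast-band event inside a dwell is reclassified
  sp_long <- tibble::tibble(onset_s = 3.5, event_class = "fast_spike",
                            peak_amp_uv = 6, duration_s = 0.3)
  out4 <- merge_and_classify(sp_long, rts, cfg)
  expect_identical(out4$event_class[out4$duration_s == 0.3], "rts_step")

  expect_error(merge_and_classify(sp[c(2, 1), ], rts, cfg),
               class = "cyanospike_error_unsorted_events")
})

test_that("fast spikes reach F1 >= 0.9 against ground truth on default days", {
  fs <- 1000
  sch <- default_schedule(60)
  f1 <- numeric(0)
  for (s in 1:200) {
    i <- (s - 1) %% 6 + 1
    sub <- condition_schedule(list(sch[[i]]))
    sim <- synthesize_schedule(sub, fs_hz = fs, seed = 6000 + s)
    a <- analyze_trace(sim$trace[[1]])
    det <- a$events[a$events$event_class == "fast_spike", ]
    truth <- sim$events[[1]]
    truth <- truth[truth$event_class == "fast_spike", ]
    if (nrow(truth) == 0) next
    f1 <- c(f1, f1_score(match_events(det, truth)))
  }
  expect_gt(mean(f1), 0.9)
})
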