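# Photometry dff, EMG labelling, rolling correlation, event-triggered and
# spectral analyses against closed-form / construction oracles.

test_that("dff is zero for a fitted reference, exact for known baselines,
           and removes shared artifacts", {
  tt <- seq(0, 60, by = 0.02)
  ref <- 100 + 5 * sin(2 * pi * 0.05 * tt)
  d <- compute_dff(tibble::tibble(signal = 2 * ref + 7, reference = ref))
  expect_lt(max(abs(d$dff)), 1e-12)
  # a 10% bump over the fitted baseline reads out as dff = 0.1
  ref2 <- 100 + sin(1:200)
  f2 <- ref2
  f2[50] <- ref2[50] * 1.1
  d2 <- compute_dff(f2, ref2)
  expect_equal(d2$dff, (f2 - d2$f0) / d2$f0)  # the defining identity
  expect_equal(d2$dff[50], 0.1, tolerance = 0.01)
  # shared artifact regressed out
  withr::with_seed(31, {
    cors <- vapply(1:10, function(i) {
      art <- spindlr:::pink_noise(5000, 2)
      ca <- pmax(0, spindlr:::pink_noise(5000, 1))
      f <- 200 + 10 * ca + 8 * art + rnorm(5000, sd = 0.1)
      fr <- 120 + 4.8 * art + rnorm(5000, sd = 0.1)
      abs(cor(compute_dff(f, fr)$dff, art))
    }, numeric(1))
  })
  expect_lt(mean(cors), 0.1)
  # invariance to affine rescaling of the reference
  withr::with_seed(32, {
    f <- 150 + rnorm(2000); fr <- 90 + rnorm(2000)
  })
  expect_equal(compute_dff(f, fr)$dff, compute_dff(f, 3 * fr + 11)$dff,
               tolerance = 1e-9)
  expect_error(compute_dff(f, rep(5, 2000)), "variance")
})

test_that("movement labelling is quiet on stationary noise and fires on
           bursts", {
  fs <- 200
  withr::with_seed(33, {
    fracs <- vapply(1:10, function(i) {
      lab <- movement_labels(rnorm(600 * fs), fs)
      mean(lab$movement)
    }, numeric(1))
  })
  expect_lt(mean(fracs), 0.05)
  # injected 20x burst in epoch 4
  withr::with_seed(34, {
    emg <- rnorm(600 * fs)
  })
  i0 <- 35 * fs
  emg[i0:(i0 + fs)] <- emg[i0:(i0 + fs)] * 20
  lab <- movement_labels(emg, fs)
  expect_true(lab$movement[4])
  # all-zero EMG: degenerate threshold, no movement
  expect_warning(lab0 <- movement_labels(numeric(100 * fs), fs), "degenerate")
  expect_true(attr(lab0, "degenerate"))
  expect_false(any(lab0$movement))
})

test_that("rectified half-wave sine has mean A/pi after low-pass", {
  fs <- 500
  tt <- (seq_len(60 * fs) - 1) / fs
  A <- 3
  y <- rectify_lowpass(A * sin(2 * pi * 5 * tt), fs, cutoff = 2)
  expect_equal(mean(y[(10 * fs):(50 * fs)]), A / pi, tolerance = 0.02)
  # nonnegative slow input passes through
  slow <- 1 + 0.5 * sin(2 * pi * 0.2 * tt)
  out <- rectify_lowpass(slow, fs, cutoff = 100)
  expect_equal(out[(fs):(59 * fs)], slow[(fs):(59 * fs)], tolerance = 0.01)
  # pure negative input vanishes
  expect_lt(max(abs(rectify_lowpass(rep(-2, 10 * fs), fs, 2))), 1e-6)
  expect_error(rectify_lowpass(slow, fs, 400), "cutoff")
})

test_that("rolling Pearson r hits the +-1 bounds and the null", {
  fs <- 100
  withr::with_seed(35, {
    x <- rnorm(600 * fs)
  })
  expect_true(all(abs(rolling_pearson(x, x, fs)$r - 1) < 1e-9))
  expect_true(all(abs(rolling_pearson(x, -x, fs)$r + 1) < 1e-9))
  withr::with_seed(36, {
    m <- vapply(1:10, function(i)
      mean(rolling_pearson(rnorm(600 * fs), rnorm(600 * fs), fs)$r),
      numeric(1))
  })
  expect_lt(max(abs(m)), 0.05)
})

test_that("relative sigma power trace separates tones and resolves 1 Hz
           entrainment", {
  fs <- 500
  tt <- (seq_len(30 * fs) - 1) / fs
  expect_gt(median(relative_band_power_trace(sin(2 * pi * 12 * tt), fs)$relpow),
            0.9)
  expect_lt(median(relative_band_power_trace(sin(2 * pi * 3 * tt), fs)$relpow),
            0.1)
  # 1 Hz-entrained bursts: periodic peaks at 1 s spacing
  ent <- simulate_entrained_nrem(n_blocks = 3, seed = 37)
  rp <- relative_band_power_trace(ent$eeg, ent$fs)
  pk <- pracma::findpeaks(rp$relpow, minpeakdistance = 5,
                          minpeakheight = max(rp$relpow) / 3)
  spacing <- diff(sort(rp$t[pk[, 2]]))
  expect_equal(median(spacing), 1, tolerance = 0.15)
  expect_true(all(rp$relpow >= 0 & rp$relpow <= 1))
})

test_that("event-triggered averaging recovers construction latencies", {
  fs <- 50
  # deterministic kernel peaking at 0.30 s
  withr::with_seed(38, {
    x <- rnorm(600 * fs, sd = 0.05)
  })
  onsets <- seq(2, 590, by = 4)
  k <- spindlr:::alpha_kernel(fs, 0.30, span = 2)
  for (o in onsets) x <- spindlr:::add_kernel_at(x, fs, o, k, 1)
  et <- event_triggered(x, fs, onsets)
  expect_equal(et$latency_to_peak, 0.30, tolerance = 1 / fs + 1e-9)
  expect_equal(et$n_events, length(onsets))
  # flat signal: degenerate
  etf <- event_triggered(rep(1, 1000), fs, c(5, 10))
  expect_true(etf$degenerate)
  expect_true(is.na(etf$latency_to_peak))
  expect_error(event_triggered(x, fs, 1e5), "events")
  # generator latencies {0.25, 0.35, 0.45} recovered within 0.04 s
  for (L in c(0.25, 0.35, 0.45)) {
    errs <- vapply(1:20, function(s) {
      cfg <- pure_state_config("nrem", 240, photo_rate = fs,
                               nrem_rebound_latency = L, seed = s)
      hyp <- generate_hypnogram(cfg)
      stim <- tibble::tibble(onset = seq(5, 230, by = 3), width = 0.2)
      ph <- generate_photometry(hyp, cfg, stim = stim)
      d <- compute_dff(tibble::tibble(signal = ph$signal,
                                      reference = ph$reference))
      event_triggered(d$dff, fs, stim$onset)$latency_to_peak - L
    }, numeric(1))
    expect_lte(mean(abs(errs)), 0.04)
  }
})

test_that("cross-correlogram shows pulse-locked structure and a clean null", {
  fs <- 10  # relpow-trace-like series resolution
  tt <- seq(0, 600, by = 1 / fs)
  # response peaking 0.3 s after each 1 Hz pulse
  series <- tibble::tibble(t = tt, v = cos(2 * pi * (tt - 0.3)))
  pulses <- seq(10, 590, by = 1)
  xc <- cross_correlogram(series, pulses, max_lag = 10)
  expect_equal(count_correlogram_peaks(xc, c(0, 10)), 10)
  # sign-flipped response: troughs where the peaks were
  xc_neg <- cross_correlogram(dplyr::mutate(series, v = -.data$v), pulses,
                              max_lag = 10)
  at_peak_lags <- xc_neg$r[abs((xc_neg$lag - 0.3) %% 1) < 1e-9 &
                             xc_neg$lag >= 0]
  expect_true(all(at_peak_lags < 0))
  # independent series: max |corr| below 3x the shuffled-pulse null SD
  withr::with_seed(39, {
    series2 <- tibble::tibble(t = tt, v = rnorm(length(tt)))
    xc2 <- cross_correlogram(series2, pulses, max_lag = 10)
    null_sd <- sd(vapply(1:20, function(i) {
      shuf <- sort(runif(length(pulses), 0, 600))
      max(abs(cross_correlogram(series2, shuf, max_lag = 10)$r))
    }, numeric(1)))
    null_max <- mean(vapply(1:20, function(i) {
      shuf <- sort(runif(length(pulses), 0, 600))
      max(abs(cross_correlogram(series2, shuf, max_lag = 10)$r))
    }, numeric(1)))
  })
  expect_lt(max(abs(xc2$r)), null_max + 3 * null_sd)
  expect_error(cross_correlogram(series, numeric(0)), "pulses")
})

test_that("two-photon pipeline flattens pure bleach and recovers transients", {
  tt <- 1:1000
  bleach <- 50 * exp(-tt / 400) + 10
  out <- twophoton_dff(bleach, stim_onset = 100)
  expect_lt(max(abs(out$dff)), 0.01)
  # exponential x (1 + boxcar): recovers the boxcar height within 5%
  box <- ifelse(tt >= 500 & tt < 560, 0.25, 0)
  out2 <- twophoton_dff(bleach * (1 + box), stim_onset = 100)
  plateau <- mean(out2$dff[515:550])
  expect_equal(plateau, 0.25, tolerance = 0.05)
  expect_lt(mean(abs(out2$dff[1:90])), 0.02)
  expect_error(twophoton_dff(bleach, stim_onset = 5), "stim_onset")
})
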