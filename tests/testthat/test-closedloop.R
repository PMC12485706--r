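# Closed-loop protocol simulation: staging rules, pulse bookkeeping,
# causality, and condition contrasts.

test_that("the spectral stager classifies canonical synthetic epochs", {
  fs <- 500
  mk_epoch <- function(state, seed) {
    cfg <- pure_state_config(state, 100, seed = seed)
    hyp <- generate_hypnogram(cfg)
    list(eeg = generate_eeg(hyp, cfg)$trace[1:(10 * fs)],
         emg = generate_emg(hyp, cfg)$trace[1:(10 * fs)])
  }
  # wake epoch containing a movement burst
  w <- mk_epoch("wake", 3)
  expect_equal(spectral_stage(w$eeg, w$emg, fs, fs), "wake")
  n <- mk_epoch("nrem", 3)
  expect_equal(spectral_stage(n$eeg, n$emg, fs, fs), "nrem")
  r <- mk_epoch("rem", 3)
  expect_equal(spectral_stage(r$eeg, r$emg, fs, fs), "rem")
  expect_error(spectral_stage(numeric(0), w$emg, fs, fs), "missing")
})

test_that("pulse counts follow floor(block_len x pulse_rate) and causality
           holds", {
  cfg <- pure_state_config("nrem", 200, photo_rate = 50, seed = 5)
  sess <- generate_session(cfg)
  sch <- tibble::tibble(win_start = 0, win_end = 200, trigger_state = "nrem",
                        channels = list("stim"))
  for (rate in c(0.5, 1, 1.5)) {
    log <- run_protocol(sess, stim_protocol(sch, pulse_rate = rate))
    per_block <- vapply(seq_len(nrow(log$blocks)), function(i)
      sum(log$pulses$onset >= log$blocks$start[i] - 1e-9 &
            log$pulses$onset < log$blocks$end[i] - 1e-9), numeric(1))
    expect_true(all(per_block == floor(10 * rate)))
  }
  # no pulse precedes its trigger
  log1 <- run_protocol(sess, stim_protocol(sch, pulse_rate = 1))
  for (i in seq_len(nrow(log1$blocks))) {
    trig <- max(log1$triggers$time[log1$triggers$time <= log1$blocks$start[i]])
    expect_gt(min(log1$pulses$onset[log1$pulses$onset >=
                                      log1$blocks$start[i]]), trig)
  }
  # trigger state never occurs: empty log
  sch_rem <- dplyr::mutate(sch, trigger_state = "rem")
  expect_equal(nrow(run_protocol(sess, stim_protocol(sch_rem))$pulses), 0)
  # overlapping pulses rejected at protocol construction
  expect_error(stim_protocol(sch, pulse_rate = 1.5, pulse_width = 0.9),
               "overlap")
})

test_that("halves protocol runs stim and stim+inhibit conditions
           concurrently", {
  cfg <- pure_state_config("nrem", 400, photo_rate = 50, seed = 6)
  sess <- generate_session(cfg)
  log <- run_protocol(sess, protocol_halves(400, pulse_rate = 1))
  expect_setequal(unique(log$pulses$condition), c("stim", "inhibit+stim"))
  inh <- log$pulses[log$pulses$channel == "inhibit", ]
  expect_true(all(inh$width == 10))
  expect_true(all(inh$onset >= 200))
  stim_second <- log$pulses[log$pulses$channel == "stim" &
                              log$pulses$onset >= 200, ]
  expect_gt(nrow(stim_second), 0)  # stim continues alongside inhibition
  # no overlapping pulses within a channel
  st <- sort(log$pulses$onset[log$pulses$channel == "stim"])
  expect_true(all(diff(st) >= 0.2 - 1e-9))
})

test_that("thirds protocol restricts each trigger to its window", {
  cfg <- synth_config(total_duration = 1800, photo_rate = 50, seed = 7)
  sess <- generate_session(cfg)
  log <- run_protocol(sess, protocol_thirds(1800, pulse_rate = 1))
  hyp <- sess$truth$hypnogram
  if (nrow(log$blocks) > 0) {
    for (i in seq_len(nrow(log$blocks))) {
      b <- log$blocks[i, ]
      # the epoch that triggered this block matches the window's state
      ep <- which(hyp$t0 == b$start - 10 - 1 / 500)
      win <- findInterval(b$start - 10 - 1 / 500, c(0, 600, 1200, 1800),
                          rightmost.closed = TRUE)
      expect_equal(as.character(hyp$state[ep]),
                   c("rem", "wake", "nrem")[win])
    }
  }
})

test_that("condition contrasts recover injected spindle effects and stay
           null for identical inputs", {
  mk_events <- function(subjects, dur_shift = 0, rate = 12, seed = 1) {
    withr::with_seed(seed, {
      purrr::map_dfr(subjects, function(s) {
        n <- rpois(1, rate) + 3
        tibble::tibble(
          subject = s,
          start = sort(runif(n, 0, 690)),
          duration = runif(n, 0.6, 1.4) + dur_shift,
          oscillations = rpois(n, 10) + 1,
          p2p_amplitude = rnorm(n, 4e-4, 5e-5),
          abs_power = rnorm(n, -8, 0.3),
          rel_power = runif(n, 0.5, 0.9),
          frequency = runif(n, 10, 14),
          symmetry = runif(n, 0.3, 0.7)
        ) |> dplyr::mutate(end = start + duration)
      })
    })
  }
  subjects <- paste0("m", 1:8)
  epochs <- purrr::map_dfr(subjects, function(s)
    tibble::tibble(subject = s, t0 = seq(0, 690, by = 10), max_abs = 1e-4))
  a <- mk_events(subjects, seed = 1)
  res0 <- compare_conditions(a, a, epochs, epochs)
  expect_true(all(res0$mean_diff == 0))
  # duration + 0.2 s in condition B: detected on duration, null elsewhere
  b <- dplyr::mutate(a, duration = duration + 0.2, end = start + duration)
  res1 <- suppressWarnings(
    compare_conditions(a, b, epochs, epochs, sided = "one"))
  expect_lt(res1$p.value[res1$characteristic == "duration"], 0.01)
  expect_gt(res1$p.value[res1$characteristic == "frequency"], 0.2)
  expect_equal(res1$mean_diff[res1$characteristic == "duration"], 0.2)
  # longer + more numerous spindles under inhibition, 10 seeds
  hits <- vapply(1:10, function(s) {
    ctrl <- mk_events(subjects, seed = s)
    inhib <- mk_events(subjects, dur_shift = 0.3, rate = 20, seed = s + 100)
    r <- suppressWarnings(
      compare_conditions(ctrl, inhib, epochs, epochs, sided = "one"))
    c(dur = r$mean_diff[r$characteristic == "duration"] > 0 &
        r$p.value[r$characteristic == "duration"] < 0.05,
      n = r$mean_diff[r$characteristic == "n_per_10s"] > 0)
  }, logical(2))
  expect_gte(mean(hits["dur", ]), 0.9)
  expect_gte(mean(hits["n", ]), 0.9)
  # amplitude exclusion drops the constructed violator epochs
  ep2 <- epochs
  ep2$max_abs[ep2$subject == "m1"] <- 1e-2
  resx <- compare_conditions(a, a, ep2, ep2)
  expect_true(all(is.finite(resx$mean_diff) | is.na(resx$mean_diff)))
  # mismatched subjects error
  expect_error(compare_conditions(a, a, epochs,
                                  dplyr::filter(epochs, subject != "m1")),
               "matched")
})
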