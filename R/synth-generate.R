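# Seeded synthetic session generators: hypnogram, EEG with embedded spindles,
# EMG with movement bursts, and two-channel fiber photometry with
# state-dependent stimulation responses. Every generator draws from a
# deterministic sub-stream of (seed, component name), so a (config, seed)
# pair fully determines the output.

STATES <- c("wake", "nrem", "rem")

#' Generate a wake/NREM/REM hypnogram
#'
#' Semi-Markov chain over wake, NREM and REM on a 10 s epoch grid. Bout
#' lengths are geometric in epochs with the configured mean dwell; REM is
#' entered only from NREM (with probability `rem_entry_prob`), and both REM
#' and NREM return paths lead through the chain wake -> NREM -> (REM ->)
#' wake. States with zero dwell are never entered; an infinite dwell pins the
#' chain.
#'
#' @param config a [synth_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return a tibble with one row per 10 s epoch: `epoch`, `t0`, `state`.
#' @export
generate_hypnogram <- function(config, seed = config$seed) {
  n_epochs <- floor(config$total_duration / EPOCH_LEN)
  if (n_epochs < 10) abort("total_duration must cover at least 10 epochs")
  dm <- config$state_dwell_means / EPOCH_LEN  # mean dwells in epochs
  if (all(dm <= 0)) abort("at least one state dwell must be positive")
  withr::with_seed(sub_seed(seed, "hypnogram"), {
    labels <- character(0)
    state <- "wake"
    next_state <- function(state) {
      switch(state,
        wake = "nrem",
        nrem = if (dm[["rem"]] > 0 && runif(1) < config$rem_entry_prob)
                 "rem" else "wake",
        rem = "wake"
      )
    }
    while (length(labels) < n_epochs) {
      m <- dm[[state]]
      if (m <= 0) {  # zero-dwell states are passed through, never emitted
        state <- next_state(state)
        next
      }
      k <- if (is.infinite(m)) {
        n_epochs - length(labels)
      } else {
        1L + rgeom(1, 1 / max(1, m))
      }
      labels <- c(labels, rep(state, k))
      state <- next_state(state)
    }
    labels <- labels[seq_len(n_epochs)]
  })
  tibble::tibble(
    epoch = seq_len(n_epochs),
    t0 = (seq_len(n_epochs) - 1) * EPOCH_LEN,
    state = factor(labels, levels = STATES)
  )
}

# Contiguous bouts of one state as half-open [start, end) intervals (s).
state_bouts <- function(hyp, state) {
  in_state <- hyp$state == state
  r <- rle(as.vector(in_state))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(
    start = hyp$t0[starts[keep]],
    end = hyp$t0[ends[keep]] + EPOCH_LEN
  )
}

state_at_time <- function(hyp, t) {
  idx <- pmin(nrow(hyp), pmax(1L, floor(t / EPOCH_LEN) + 1L))
  as.character(hyp$state[idx])
}

# Poisson-place non-overlapping events of given durations inside [start, end),
# keeping a margin between events; simple rejection sampling.
place_events <- function(bout_start, bout_end, rate_per_min, dur_range,
                         margin = 0.2) {
  len <- bout_end - bout_start
  n <- rpois(1, rate_per_min / 60 * len)
  if (n == 0) return(tibble::tibble(start = numeric(0), end = numeric(0)))
  placed <- tibble::tibble(start = numeric(0), end = numeric(0))
  for (i in seq_len(n)) {
    d <- runif(1, dur_range[1], dur_range[2])
    if (d >= len) next
    for (try in 1:50) {
      s <- bout_start + runif(1, 0, len - d)
      if (nrow(placed) == 0 ||
          all(s >= placed$end + margin | s + d <= placed$start - margin)) {
        placed <- dplyr::bind_rows(placed, tibble::tibble(start = s, end = s + d))
        break
      }
    }
  }
  dplyr::arrange(placed, .data$start)
}

spindle_burst <- function(fs, dur, freq, amp, phase = 0) {
  n <- round(dur * fs)
  tt <- seq_len(n) / fs
  amp * hann_window(n) * sin(2 * pi * freq * tt + phase)
}

#' Generate a synthetic EEG trace with embedded spindles
#'
#' 1/f background everywhere; NREM epochs additionally carry a delta-band
#' (2 Hz) oscillation and Poisson-placed spindle bursts (constant-frequency
#' sinusoid with a Hann waxing-and-waning envelope, frequency and duration
#' uniform in the configured ranges, peak amplitude `spindle_amp_snr` times
#' the background RMS). REM epochs carry a theta (7 Hz) oscillation. Returns
#' the ground-truth spindle intervals.
#'
#' @inheritParams generate_hypnogram
#' @param hyp hypnogram tibble from [generate_hypnogram()].
#' @return list with `trace` (numeric, volts), `fs`, and `spindle_intervals`
#'   (tibble: start, end, freq).
#' @export
generate_eeg <- function(hyp, config, seed = config$seed) {
  fs <- config$eeg_rate
  if (fs < 100) abort("eeg_rate must be at least 100 Hz")
  if (config$spindle_freq_range[2] >= fs / 2)
    abort("spindle_freq_range exceeds Nyquist")
  n <- round(nrow(hyp) * EPOCH_LEN * fs)
  rms <- config$eeg_rms
  withr::with_seed(sub_seed(seed, "eeg"), {
    trace <- pink_noise(n, config$noise_exponent) * rms
    tt <- (seq_len(n) - 1) / fs
    nrem_mask <- state_at_time(hyp, tt) == "nrem"
    rem_mask <- state_at_time(hyp, tt) == "rem"
    trace <- trace + 1.2 * rms * sin(2 * pi * 2 * tt) * nrem_mask
    trace <- trace + 1.2 * rms * sin(2 * pi * 7 * tt) * rem_mask
    bouts <- state_bouts(hyp, "nrem")
    spindles <- purrr::pmap_dfr(bouts, function(start, end) {
      ev <- place_events(start, end, config$spindle_rate_nrem,
                         config$spindle_dur_range)
      ev$freq <- runif(nrow(ev), config$spindle_freq_range[1],
                       config$spindle_freq_range[2])
      ev
    })
    if (nrow(spindles) == 0)
      spindles <- tibble::tibble(start = numeric(0), end = numeric(0),
                                 freq = numeric(0))
    if (nrow(spindles) > 0) {
      for (i in seq_len(nrow(spindles))) {
        i0 <- round(spindles$start[i] * fs) + 1L
        burst <- spindle_burst(fs, spindles$end[i] - spindles$start[i],
                               spindles$freq[i],
                               config$spindle_amp_snr * rms,
                               phase = runif(1, 0, 2 * pi))
        idx <- i0:(i0 + length(burst) - 1L)
        ok <- idx <= n
        trace[idx[ok]] <- trace[idx[ok]] + burst[ok]
      }
    }
    list(trace = trace, fs = fs, spindle_intervals = spindles)
  })
}

#' Generate a synthetic EMG trace with wake movement bursts
#'
#' Gaussian baseline noise everywhere (attenuated during NREM and further
#' during REM atonia); wake bouts receive Hann-enveloped noise bursts of gain
#' `emg_burst_gain` at `emg_burst_rate_wake` per minute. Returns ground-truth
#' movement intervals.
#'
#' @inheritParams generate_eeg
#' @return list with `trace` (numeric, volts), `fs`, and `movement_intervals`
#'   (tibble: start, end).
#' @export
generate_emg <- function(hyp, config, seed = config$seed) {
  fs <- config$emg_rate
  if (fs < 100) abort("emg_rate must be at least 100 Hz")
  n <- round(nrow(hyp) * EPOCH_LEN * fs)
  rms <- config$emg_rms
  withr::with_seed(sub_seed(seed, "emg"), {
    tt <- (seq_len(n) - 1) / fs
    st <- state_at_time(hyp, tt)
    scale <- c(wake = 1, nrem = 0.6, rem = 0.4)[st]
    trace <- rnorm(n) * rms * scale
    bouts <- state_bouts(hyp, "wake")
    moves <- purrr::pmap_dfr(bouts, function(start, end) {
      place_events(start, end, config$emg_burst_rate_wake, c(0.3, 1.5))
    })
    if (nrow(moves) == 0)
      moves <- tibble::tibble(start = numeric(0), end = numeric(0))
    if (nrow(moves) > 0) {
      for (i in seq_len(nrow(moves))) {
        i0 <- round(moves$start[i] * fs) + 1L
        m <- round((moves$end[i] - moves$start[i]) * fs)
        idx <- i0:(i0 + m - 1L)
        ok <- idx <= n
        env <- hann_window(m) * config$emg_burst_gain * rms
        trace[idx[ok]] <- trace[idx[ok]] + env[ok] * rnorm(sum(ok))
      }
    }
    list(trace = trace, fs = fs, movement_intervals = moves)
  })
}

# Calcium indicator kernel, peak-normalized; and an alpha kernel whose
# maximum sits exactly at `latency` seconds.
ca_kernel_fn <- function(fs, rise, decay, span = NULL) {
  span <- span %||% (5 * decay)
  tt <- seq(0, span, by = 1 / fs)
  k <- (1 - exp(-tt / rise)) * exp(-tt / decay)
  k / max(k)
}

alpha_kernel <- function(fs, latency, span = NULL) {
  span <- span %||% (latency + 3)
  tt <- seq(0, span, by = 1 / fs)
  (tt / latency) * exp(1 - tt / latency)
}

add_kernel_at <- function(trace, fs, onset, kernel, amp) {
  i0 <- round(onset * fs) + 1L
  idx <- i0:(i0 + length(kernel) - 1L)
  ok <- idx >= 1 & idx <= length(trace)
  trace[idx[ok]] <- trace[idx[ok]] + amp * kernel[ok]
  trace
}

#' Generate two-channel synthetic fiber photometry
#'
#' The signal channel carries a latent calcium trace (Poisson transient train
#' convolved with the indicator kernel) plus state-dependent responses to
#' stimulation pulses: during NREM a rebound transient peaking exactly
#' `nrem_rebound_latency` seconds after pulse onset; during wake/REM a
#' suppression (negative deflection) scaled by `wake_rem_suppression_gain`.
#' Both channels share a slow motion artifact; only the signal channel
#' carries calcium responses, so regressing the reference out recovers the
#' latent trace.
#'
#' @inheritParams generate_eeg
#' @param stim optional tibble of stimulation pulses (`onset`, `width`, s);
#'   pulses outside the recording raise an error.
#' @return list with `signal`, `reference` (numeric, fluorescence a.u.),
#'   `fs`, and `latent_dff` (the injected fractional-change trace).
#' @export
generate_photometry <- function(hyp, config, stim = NULL, seed = config$seed) {
  fs <- config$photo_rate
  if (fs < 20) abort("photo_rate must be at least 20 Hz")
  dur <- nrow(hyp) * EPOCH_LEN
  n <- round(dur * fs)
  if (!is.null(stim) && nrow(stim) > 0 &&
      (any(stim$onset < 0) || any(stim$onset + stim$width > dur)))
    abort("stimulation pulses fall outside the recording")
  withr::with_seed(sub_seed(seed, "photometry"), {
    s <- numeric(n)
    kern <- ca_kernel_fn(fs, config$ca_kernel[["rise"]],
                         config$ca_kernel[["decay"]])
    n_ev <- rpois(1, config$ca_event_rate / 60 * dur)
    if (n_ev > 0) {
      onsets <- sort(runif(n_ev, 0, dur))
      for (o in onsets) s <- add_kernel_at(s, fs, o, kern, 0.03 * runif(1, .5, 1.5))
    }
    if (!is.null(stim) && nrow(stim) > 0) {
      reb <- alpha_kernel(fs, config$nrem_rebound_latency)
      sup <- alpha_kernel(fs, 0.3, span = 2)
      states <- state_at_time(hyp, stim$onset)
      for (i in seq_len(nrow(stim))) {
        if (states[i] == "nrem") {
          s <- add_kernel_at(s, fs, stim$onset[i], reb, 0.05)
        } else {
          s <- add_kernel_at(s, fs, stim$onset[i], sup,
                             -0.03 * config$wake_rem_suppression_gain)
        }
      }
    }
    artifact <- pink_noise(n, 2)
    signal <- 200 * (1 + s) + 4 * artifact + rnorm(n, sd = 0.2)
    reference <- 120 + 2.4 * artifact + rnorm(n, sd = 0.15)
    list(signal = signal, reference = reference, fs = fs, latent_dff = s)
  })
}

#' Generate a complete synthetic session with ground truth
#'
#' Bundles the hypnogram, bilateral EEG, bilateral EMG and two-channel
#' photometry generators on one time base. The second EEG/EMG channels are
#' attenuated copies of the first with independent noise (two recording
#' screws / two electrodes over the same sources). Deterministic per
#' (config, seed).
#'
#' @inheritParams generate_photometry
#' @param config a [synth_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return a `synth_session`: list with `recording` (list of channel tibbles
#'   `eeg`, `emg`, `photo`, plus `rates`) and `truth` (hypnogram, spindle,
#'   movement and stimulation ground truth).
#' @export
generate_session <- function(config, seed = config$seed, stim = NULL) {
  stopifnot(inherits(config, "synth_config"))
  hyp <- generate_hypnogram(config, seed)
  eeg <- generate_eeg(hyp, config, seed)
  emg <- generate_emg(hyp, config, seed)
  photo <- generate_photometry(hyp, config, stim = stim, seed = seed)
  n_eeg <- length(eeg$trace)
  n_emg <- length(emg$trace)
  second <- withr::with_seed(sub_seed(seed, "second-channels"), {
    list(eeg_L = 0.9 * eeg$trace + 0.3 * config$eeg_rms * rnorm(n_eeg),
         emg_2 = 0.9 * emg$trace + 0.3 * config$emg_rms * rnorm(n_emg))
  })
  recording <- list(
    eeg = tibble::tibble(t = (seq_len(n_eeg) - 1) / eeg$fs,
                         eeg_R = eeg$trace, eeg_L = second$eeg_L),
    emg = tibble::tibble(t = (seq_len(n_emg) - 1) / emg$fs,
                         emg_1 = emg$trace, emg_2 = second$emg_2),
    photo = tibble::tibble(t = (seq_len(length(photo$signal)) - 1) / photo$fs,
                           signal = photo$signal, reference = photo$reference),
    rates = list(eeg = eeg$fs, emg = emg$fs, photo = photo$fs)
  )
  truth <- list(
    hypnogram = hyp,
    spindle_intervals = eeg$spindle_intervals,
    movement_intervals = emg$movement_intervals,
    stim_pulses = stim %||% tibble::tibble(onset = numeric(0), width = numeric(0)),
    latent_response_latency = config$nrem_rebound_latency,
    latent_dff = photo$latent_dff
  )
  structure(list(recording = recording, truth = truth, config = config,
                 seed = seed),
            class = "synth_session")
}

#' @export
print.synth_session <- function(x, ...) {
  hyp <- x$truth$hypnogram
  cat(sprintf("<synth_session> %d epochs (%.1f min): %s\n",
              nrow(hyp), nrow(hyp) * EPOCH_LEN / 60,
              paste(sprintf("%s %.0f%%", STATES,
                            100 * prop.table(table(hyp$state))[STATES]),
                    collapse = ", ")))
  cat(sprintf("  %d ground-truth spindles, %d movement bursts, %d stim pulses\n",
              nrow(x$truth$spindle_intervals),
              nrow(x$truth$movement_intervals),
              nrow(x$truth$stim_pulses)))
  invisible(x)
}
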