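# Shared fixture builders: NREM-like EEG background, sigma bursts, and the
# event-matching oracle used to score detections against ground truth.

FS_TEST <- 500

# 1/f background plus the delta oscillation characteristic of NREM EEG.
nrem_background <- function(total_s, fs = FS_TEST, delta_amp = 1.2) {
  n <- total_s * fs
  x <- spindlr:::pink_noise(n)
  tt <- (seq_len(n) - 1) / fs
  x + delta_amp * sin(2 * pi * 2 * tt)
}

# Add one Hann-enveloped sigma burst at `at` seconds, peak amplitude `snr`
# times the unit background RMS.
add_burst <- function(x, dur, freq, at, snr = 4, fs = FS_TEST, phase = 0) {
  n <- round(dur * fs)
  tt <- seq_len(n) / fs
  b <- snr * spindlr:::hann_window(n) * sin(2 * pi * freq * tt + phase)
  i0 <- round(at * fs) + 1L
  x[i0:(i0 + n - 1L)] <- x[i0:(i0 + n - 1L)] + b
  x
}

# Greedy event matching at a minimum fractional overlap of the true event;
# returns precision/recall/F1.
match_events <- function(detected, truth, min_overlap = 0.5) {
  if (nrow(truth) == 0) {
    return(list(tp = 0, fp = nrow(detected), fn = 0,
                precision = NA, recall = NA, f1 = NA))
  }
  if (nrow(detected) == 0) {
    return(list(tp = 0, fp = 0, fn = nrow(truth),
                precision = NA, recall = 0, f1 = 0))
  }
  ov <- outer(seq_len(nrow(detected)), seq_len(nrow(truth)),
              Vectorize(function(i, j) {
                inter <- min(detected$end[i], truth$end[j]) -
                  max(detected$start[i], truth$start[j])
                max(0, inter) / (truth$end[j] - truth$start[j])
              }))
  tp <- sum(apply(ov, 2, max) >= min_overlap)
  fp <- sum(apply(ov, 1, max) < min_overlap)
  fn <- nrow(truth) - tp
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = 2 * precision * recall / max(precision + recall, 1e-12))
}

# Single-state configs used across tests.
pure_state_config <- function(state, total_duration, ...) {
  dw <- c(wake = 0, nrem = 0, rem = 0)
  dw[state] <- Inf
  synth_config(total_duration = total_duration, state_dwell_means = dw, ...)
}

# Synthetic five-feature epoch table with a separable class signal per
# subject; used by the decoding tests.
make_decode_data <- function(n_subjects = 5, n_epochs = 40, effect = 3,
                             seed = 1) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_subjects), function(s) {
      lab <- rep(c(TRUE, FALSE), length.out = n_epochs)
      tibble::tibble(
        std = rnorm(n_epochs) + effect * lab,
        mad = rnorm(n_epochs) + 0.5 * effect * lab,
        iqr = rnorm(n_epochs),
        rms_dx = rnorm(n_epochs),
        `pow_0.2_0.5` = runif(n_epochs),
        label = lab,
        subject = paste0("m", s)
      )
    })
  })
}
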