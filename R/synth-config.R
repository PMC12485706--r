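# Configuration for the synthetic polysomnography + photometry generator.

EPOCH_LEN <- 10  # s; the staging epoch grid used throughout

#' Synthetic session configuration
#'
#' Builds and validates the parameter set for the synthetic session
#' generators. Defaults model a mouse polysomnography session: EEG/EMG at
#' 500 Hz, photometry at 1 kHz, 9-16 Hz spindles of 0.5-2 s at four times the
#' background RMS occurring at 6 events/min during NREM, EMG movement bursts
#' in wake, and calcium responses that rebound ~0.45 s after stimulation in
#' NREM but are suppressed in wake/REM.
#'
#' @param total_duration session length, s.
#' @param eeg_rate,emg_rate,photo_rate channel sampling rates, Hz.
#' @param state_dwell_means named numeric (wake, nrem, rem): mean bout
#'   durations, s. `Inf` pins the chain in that state.
#' @param rem_entry_prob probability that a NREM bout is followed by REM
#'   (REM is entered only from NREM).
#' @param spindle_rate_nrem spindle events per minute of NREM.
#' @param spindle_freq_range,spindle_dur_range spindle frequency (Hz) and
#'   duration (s) ranges, sampled uniformly per event.
#' @param spindle_amp_snr spindle peak amplitude as a multiple of the
#'   background EEG RMS.
#' @param noise_exponent spectral slope of the 1/f EEG background.
#' @param emg_burst_rate_wake movement bursts per minute of wake.
#' @param emg_burst_gain burst envelope gain over baseline EMG noise.
#' @param ca_kernel named numeric (rise, decay): calcium indicator kernel
#'   time constants, s.
#' @param ca_event_rate baseline calcium transients per minute.
#' @param nrem_rebound_latency latency (s) of the calcium response peak after
#'   a stimulation pulse onset during NREM.
#' @param wake_rem_suppression_gain scale of the negative (suppression)
#'   response to pulses delivered in wake or REM.
#' @param eeg_rms background EEG RMS, V.
#' @param emg_rms baseline EMG RMS, V.
#' @param seed integer; identical (config, seed) pairs give identical output.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(total_duration = 3600,
                         eeg_rate = 500, emg_rate = 500, photo_rate = 1000,
                         state_dwell_means = c(wake = 240, nrem = 180, rem = 60),
                         rem_entry_prob = 0.35,
                         spindle_rate_nrem = 6,
                         spindle_freq_range = c(9, 16),
                         spindle_dur_range = c(0.5, 2),
                         spindle_amp_snr = 4,
                         noise_exponent = 1,
                         emg_burst_rate_wake = 6,
                         emg_burst_gain = 10,
                         ca_kernel = c(rise = 0.2, decay = 1.0),
                         ca_event_rate = 10,
                         nrem_rebound_latency = 0.45,
                         wake_rem_suppression_gain = 1,
                         eeg_rms = 5e-5,
                         emg_rms = 2e-5,
                         seed = 1L) {
  check_scalar_number(total_duration, "total_duration", min = 1)
  for (nm in c("eeg_rate", "emg_rate", "photo_rate"))
    check_scalar_number(get(nm), nm, min = 1e-9)
  stopifnot(length(state_dwell_means) == 3)
  if (is.null(names(state_dwell_means)))
    names(state_dwell_means) <- c("wake", "nrem", "rem")
  if (any(state_dwell_means < 0, na.rm = TRUE))
    abort("state dwell means must be non-negative")
  check_scalar_number(rem_entry_prob, "rem_entry_prob", 0, 1)
  check_scalar_number(spindle_rate_nrem, "spindle_rate_nrem", 0)
  stopifnot(length(spindle_freq_range) == 2, length(spindle_dur_range) == 2)
  if (spindle_dur_range[1] < 0.3 || spindle_dur_range[2] > 3 ||
      spindle_dur_range[1] >= spindle_dur_range[2])
    abort("spindle_dur_range must be increasing and within [0.3, 3] s")
  if (spindle_freq_range[1] < 1 || spindle_freq_range[2] >= eeg_rate / 2 ||
      spindle_freq_range[1] >= spindle_freq_range[2])
    abort("spindle_freq_range must be increasing and within [1, eeg_rate/2) Hz")
  check_scalar_number(spindle_amp_snr, "spindle_amp_snr", 0)
  check_scalar_number(emg_burst_rate_wake, "emg_burst_rate_wake", 0)
  check_scalar_number(emg_burst_gain, "emg_burst_gain", 0)
  stopifnot(all(ca_kernel > 0), length(ca_kernel) == 2)
  check_scalar_number(nrem_rebound_latency, "nrem_rebound_latency", 0.001, 5)
  structure(
    list(total_duration = total_duration, eeg_rate = eeg_rate,
         emg_rate = emg_rate, photo_rate = photo_rate,
         state_dwell_means = state_dwell_means,
         rem_entry_prob = rem_entry_prob,
         spindle_rate_nrem = spindle_rate_nrem,
         spindle_freq_range = spindle_freq_range,
         spindle_dur_range = spindle_dur_range,
         spindle_amp_snr = spindle_amp_snr,
         noise_exponent = noise_exponent,
         emg_burst_rate_wake = emg_burst_rate_wake,
         emg_burst_gain = emg_burst_gain,
         ca_kernel = ca_kernel, ca_event_rate = ca_event_rate,
         nrem_rebound_latency = nrem_rebound_latency,
         wake_rem_suppression_gain = wake_rem_suppression_gain,
         eeg_rms = eeg_rms, emg_rms = emg_rms,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}
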