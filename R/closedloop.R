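# Simulation of state-triggered closed-loop optogenetic stimulation
# protocols against a (synthetic) recording, with a pluggable sleep stager
# standing in for a real-time classifier.

#' Define a closed-loop stimulation protocol
#'
#' A protocol is a schedule of time windows, each with a trigger state and
#' one or more light channels. When the stager reports the trigger state at
#' an epoch boundary inside a window, a 10 s block is emitted: pulsed
#' channels fire `floor(block_len * pulse_rate)` pulses of `pulse_width`,
#' continuous channels stay on for the whole block.
#'
#' @param schedule a tibble with columns `win_start`, `win_end` (s),
#'   `trigger_state` ("wake"/"nrem"/"rem") and `channels` (list-column of
#'   character vectors, or a single channel name). Windows must tile the
#'   session without overlap.
#' @param pulse_rate pulses per second for pulsed channels (0.5, 1 or 1.5 in
#'   the standard protocols).
#' @param pulse_width light-on time per pulse, s (default 0.2).
#' @param block_len stimulation block length, s (default 10).
#' @param channel_modes named character: `"pulsed"` or `"continuous"` per
#'   channel name (default: `stim` pulsed, `inhibit` continuous).
#' @return a `stim_protocol` list.
#' @export
stim_protocol <- function(schedule, pulse_rate = 1, pulse_width = 0.2,
                          block_len = 10,
                          channel_modes = c(stim = "pulsed",
                                            inhibit = "continuous")) {
  stopifnot(is.data.frame(schedule),
            all(c("win_start", "win_end", "trigger_state") %in% names(schedule)))
  if (pulse_width * pulse_rate > 1)
    abort("pulse_width x pulse_rate must not exceed 1 (pulses would overlap)")
  sch <- dplyr::arrange(tibble::as_tibble(schedule), .data$win_start)
  if (nrow(sch) > 1 && any(sch$win_start[-1] < sch$win_end[-nrow(sch)]))
    abort("schedule windows overlap")
  if (!"channels" %in% names(sch)) sch$channels <- list("stim")
  if (!is.list(sch$channels)) sch$channels <- as.list(sch$channels)
  structure(list(schedule = sch, pulse_rate = pulse_rate,
                 pulse_width = pulse_width, block_len = block_len,
                 channel_modes = channel_modes),
            class = "stim_protocol")
}

#' Day-in-thirds stimulation protocol
#'
#' The standard 24 h design: the recording is split into thirds with REM,
#' wake and NREM (in that order) as the trigger states.
#'
#' @param total_duration recording length, s.
#' @param pulse_rate pulses per second (0.5, 1 or 1.5).
#' @param states trigger states per third.
#' @param ... passed to [stim_protocol()].
#' @return a `stim_protocol`.
#' @export
protocol_thirds <- function(total_duration, pulse_rate = 1,
                            states = c("rem", "wake", "nrem"), ...) {
  edges <- seq(0, total_duration, length.out = 4)
  stim_protocol(
    tibble::tibble(win_start = edges[1:3], win_end = edges[2:4],
                   trigger_state = states, channels = list("stim")),
    pulse_rate = pulse_rate, ...)
}

#' Day-in-halves concurrent stimulation + inhibition protocol
#'
#' NREM-triggered stimulation throughout; the inhibition channel is added in
#' one half (continuous light during triggered blocks). `inhibit_first`
#' reverses the order, as in the second recording day of the design.
#'
#' @param total_duration recording length, s.
#' @param pulse_rate pulses per second.
#' @param inhibit_first logical; if TRUE the stim+inhibit half comes first.
#' @param ... passed to [stim_protocol()].
#' @return a `stim_protocol`.
#' @export
protocol_halves <- function(total_duration, pulse_rate = 1,
                            inhibit_first = FALSE, ...) {
  half <- total_duration / 2
  chans <- list(list("stim"), list(c("stim", "inhibit")))
  if (inhibit_first) chans <- rev(chans)
  stim_protocol(
    tibble::tibble(win_start = c(0, half), win_end = c(half, total_duration),
                   trigger_state = "nrem",
                   channels = c(chans[[1]], chans[[2]])),
    pulse_rate = pulse_rate, ...)
}

#' Rule-based spectral sleep stager
#'
#' Stages a 10 s epoch from its EEG and EMG: a high EMG envelope gives wake;
#' with quiet EMG, a high delta (1-4 Hz) over theta (5-9 Hz) power ratio
#' gives NREM and a theta-dominant spectrum gives REM; intermediate ratios
#' default to wake.
#'
#' @param eeg_epoch,emg_epoch numeric traces covering one 10 s epoch.
#' @param eeg_fs,emg_fs sampling rates, Hz.
#' @param emg_thresh RMS threshold (same units as the EMG) above which the
#'   epoch is wake.
#' @param delta_ratio delta/theta ratio above which a quiet epoch is NREM.
#' @param theta_ratio delta/theta ratio below which a quiet epoch is REM.
#' @return one of `"wake"`, `"nrem"`, `"rem"`.
#' @export
spectral_stage <- function(eeg_epoch, emg_epoch, eeg_fs, emg_fs,
                           emg_thresh = 2.8e-5, delta_ratio = 3,
                           theta_ratio = 1.5) {
  if (length(eeg_epoch) == 0 || length(emg_epoch) == 0)
    abort("missing EEG or EMG epoch")
  if (sqrt(mean(emg_epoch^2)) > emg_thresh) return("wake")
  delta <- mean(bandpass(eeg_epoch, eeg_fs, c(1, 4))^2)
  theta <- mean(bandpass(eeg_epoch, eeg_fs, c(5, 9))^2)
  ratio <- delta / max(theta, .Machine$double.eps)
  if (ratio > delta_ratio) "nrem" else if (ratio < theta_ratio) "rem" else "wake"
}

#' Run a closed-loop protocol against a recording
#'
#' Advances epoch by epoch (a 10 s rolling buffer); at each epoch boundary
#' the stager's state for the just-completed epoch is compared with the
#' active window's trigger state, and on a match a block of light is emitted
#' on the window's channels starting at the sample after detection. Pulsed
#' channels fire `floor(block_len * pulse_rate)` pulses; continuous channels
#' emit one block-long illumination. No light precedes its trigger.
#'
#' @param session a `synth_session` (or a compatible list with `recording`
#'   and `truth`).
#' @param protocol a [stim_protocol()].
#' @param stager `"truth"` (use the ground-truth hypnogram, isolating
#'   protocol logic from staging error) or `"spectral"`
#'   ([spectral_stage()]).
#' @param ... passed to [spectral_stage()].
#' @return a `stim_log`: `pulses` (onset, width, channel, condition),
#'   `triggers` (time, state), `blocks` (start, end, condition).
#' @export
run_protocol <- function(session, protocol, stager = c("truth", "spectral"),
                         ...) {
  stager <- match.arg(stager)
  stopifnot(inherits(protocol, "stim_protocol"))
  hyp <- session$truth$hypnogram
  rec <- session$recording
  total <- nrow(hyp) * EPOCH_LEN
  if (max(protocol$schedule$win_end) > total + 1e-9)
    abort("schedule extends beyond the recording")
  eeg_fs <- rec$rates$eeg; emg_fs <- rec$rates$emg
  dt <- 1 / eeg_fs
  n_pulses <- floor(protocol$block_len * protocol$pulse_rate)

  triggers <- list(); pulses <- list(); blocks <- list()
  for (e in seq_len(nrow(hyp))) {
    t_detect <- hyp$t0[e] + EPOCH_LEN    # decision at the epoch boundary
    if (t_detect + protocol$block_len > total) break
    win <- which(protocol$schedule$win_start <= hyp$t0[e] &
                 hyp$t0[e] < protocol$schedule$win_end)
    if (length(win) == 0) next
    state <- if (stager == "truth") {
      as.character(hyp$state[e])
    } else {
      i_eeg <- (round(hyp$t0[e] * eeg_fs) + 1):round((hyp$t0[e] + EPOCH_LEN) * eeg_fs)
      i_emg <- (round(hyp$t0[e] * emg_fs) + 1):round((hyp$t0[e] + EPOCH_LEN) * emg_fs)
      spectral_stage(rec$eeg$eeg_R[i_eeg], rec$emg$emg_1[i_emg],
                     eeg_fs, emg_fs, ...)
    }
    triggers[[length(triggers) + 1]] <-
      tibble::tibble(time = t_detect, state = state)
    if (state != protocol$schedule$trigger_state[win]) next
    chans <- protocol$schedule$channels[[win]]
    cond <- paste(sort(chans), collapse = "+")
    blocks[[length(blocks) + 1]] <-
      tibble::tibble(start = t_detect + dt,
                     end = t_detect + dt + protocol$block_len,
                     condition = cond)
    for (ch in chans) {
      mode <- protocol$channel_modes[[ch]] %||% "pulsed"
      if (mode == "continuous") {
        pulses[[length(pulses) + 1]] <-
          tibble::tibble(onset = t_detect + dt, width = protocol$block_len,
                         channel = ch, condition = cond)
      } else {
        pulses[[length(pulses) + 1]] <-
          tibble::tibble(onset = t_detect + dt + (seq_len(n_pulses) - 1) /
                           protocol$pulse_rate,
                         width = protocol$pulse_width,
                         channel = ch, condition = cond)
      }
    }
  }
  empty_p <- tibble::tibble(onset = numeric(0), width = numeric(0),
                            channel = character(0), condition = character(0))
  structure(
    list(pulses = if (length(pulses)) dplyr::bind_rows(pulses) else empty_p,
         triggers = dplyr::bind_rows(triggers),
         blocks = if (length(blocks)) dplyr::bind_rows(blocks)
                  else tibble::tibble(start = numeric(0), end = numeric(0),
                                      condition = character(0))),
    class = "stim_log"
  )
}

#' @export
print.stim_log <- function(x, ...) {
  cat(sprintf("<stim_log> %d pulses in %d blocks (%d triggers evaluated)\n",
              nrow(x$pulses), nrow(x$blocks), nrow(x$triggers)))
  invisible(x)
}

#' Compare spindle characteristics between two conditions
#'
#' Per-subject means of spindles-per-10 s and the per-event characteristics
#' (duration, oscillations, peak-to-peak amplitude, absolute and relative
#' sigma power, frequency, symmetry) are computed for two matched
#' conditions; epochs containing any sample above the amplitude exclusion
#' cap are dropped (with the events inside them), and each characteristic is
#' compared with a paired exact Wilcoxon signed-rank test.
#'
#' @param events_a,events_b event tables ([detect_spindles()] columns plus a
#'   `subject` column).
#' @param epochs_a,epochs_b epoch tables: `subject`, `t0`, `max_abs` (the
#'   maximum absolute sample value in the epoch, same units as the EEG).
#' @param amplitude_cap exclusion cap on `max_abs` (default `300e-5` V).
#' @param sided sidedness of the paired tests (default two).
#' @param epoch_len epoch length, s.
#' @return a tibble with one row per characteristic: per-condition means,
#'   mean paired difference (b - a), `statistic`, `p.value`.
#' @export
compare_conditions <- function(events_a, events_b, epochs_a, epochs_b,
                               amplitude_cap = 300e-5, sided = "two",
                               epoch_len = 10) {
  for (d in list(events_a, events_b))
    stopifnot(is.data.frame(d), "subject" %in% names(d))
  subjects <- sort(unique(epochs_a$subject))
  if (!setequal(subjects, unique(epochs_b$subject)))
    abort("subjects are not matched across conditions")

  summarise_cond <- function(events, epochs) {
    kept <- dplyr::filter(epochs, .data$max_abs <= amplitude_cap)
    purrr::map_dfr(subjects, function(s) {
      ep <- dplyr::filter(kept, .data$subject == s)
      ev <- dplyr::filter(events, .data$subject == s)
      if (nrow(ep) > 0) {
        in_kept <- vapply(ev$start, function(st)
          any(st >= ep$t0 & st < ep$t0 + epoch_len), logical(1))
        ev <- ev[in_kept, ]
      } else ev <- ev[0, ]
      tibble::tibble(
        subject = s,
        n_per_10s = if (nrow(ep) > 0) nrow(ev) / nrow(ep) else NA_real_,
        duration = mean(ev$duration), oscillations = mean(ev$oscillations),
        amplitude = mean(ev$p2p_amplitude), abs_power = mean(ev$abs_power),
        rel_power = mean(ev$rel_power), frequency = mean(ev$frequency),
        symmetry = mean(ev$symmetry)
      )
    })
  }
  a <- summarise_cond(events_a, epochs_a)
  b <- summarise_cond(events_b, epochs_b)
  chars <- setdiff(names(a), "subject")
  purrr::map_dfr(chars, function(ch) {
    d <- b[[ch]] - a[[ch]]
    ok <- is.finite(d)
    res <- if (sum(d[ok] != 0) > 0) wilcoxon_exact(d[ok], sided = sided)
           else new_exact_test(NA_real_, 1, sided, "degenerate", sum(ok))
    tibble::tibble(characteristic = ch,
                   mean_a = mean(a[[ch]][ok]), mean_b = mean(b[[ch]][ok]),
                   mean_diff = mean(d[ok]),
                   statistic = res$statistic, p.value = res$p)
  })
}
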