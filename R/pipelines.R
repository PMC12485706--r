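# Figure-level orchestration: seeded random-segment sampling with exclusion
# rules, aligned-vs-shuffled paired comparisons, and detected-vs-shuffled
# power spectral contrasts.

#' Segment sampling specification
#'
#' @param n_samples segments drawn per iteration.
#' @param segment_len segment length, s.
#' @param state_constraint hypnogram state segments must lie in (`NULL` for
#'   any).
#' @param n_iterations number of seeded sampling repetitions (default 100).
#' @param zscore_exclusion segments whose mean value exceeds this many SDs of
#'   the whole-trace distribution are excluded (`Inf` disables; 5 and 1 are
#'   the conventions for spindle-locked and stimulation-locked sampling).
#' @param amplitude_exclusion segments containing any sample above this
#'   absolute value are excluded (`Inf` disables; `300e-5` V is the EEG
#'   convention).
#' @param seed integer seed.
#' @return a `sampling_spec` list.
#' @export
sampling_spec <- function(n_samples = 10, segment_len = 2,
                          state_constraint = "nrem", n_iterations = 100,
                          zscore_exclusion = 5, amplitude_exclusion = Inf,
                          seed = 1) {
  stopifnot(n_samples >= 1, segment_len > 0, n_iterations >= 1,
            zscore_exclusion > 0, amplitude_exclusion > 0)
  structure(list(n_samples = n_samples, segment_len = segment_len,
                 state_constraint = state_constraint,
                 n_iterations = n_iterations,
                 zscore_exclusion = zscore_exclusion,
                 amplitude_exclusion = amplitude_exclusion,
                 seed = as.integer(seed)),
            class = "sampling_spec")
}

#' Sample anchored segments from a trace
#'
#' Draws `n_samples` segments per iteration, anchored on spindle centres,
#' stimulation onsets, or random times within the state constraint, without
#' replacement within an iteration. Exclusion rules are applied after
#' drawing: segment-mean z-score (against the whole-trace mean/SD) and
#' absolute amplitude cap.
#'
#' @param trace numeric trace the segments are cut from.
#' @param fs sampling rate, Hz.
#' @param hyp hypnogram tibble (`t0`, `state`).
#' @param spec a [sampling_spec()].
#' @param anchor `"spindle_center"`, `"random"`, or `"stim_onset"`.
#' @param anchors event times (s) for the non-random anchors: spindle
#'   centres or pulse onsets.
#' @return a tibble: `iteration`, `id`, `start`, `end`, `excluded`, and a
#'   list-column `segment` of the retained segment samples (`NULL` when
#'   excluded).
#' @export
sample_segments <- function(trace, fs, hyp, spec,
                            anchor = c("random", "spindle_center", "stim_onset"),
                            anchors = NULL) {
  anchor <- match.arg(anchor)
  half <- spec$segment_len / 2
  total <- nrow(hyp) * EPOCH_LEN
  if (anchor != "random") {
    if (is.null(anchors) || length(anchors) == 0)
      abort("no anchor events available")
    centers0 <- if (anchor == "spindle_center") anchors else anchors + half
    centers0 <- centers0[centers0 - half >= 0 & centers0 + half <= total]
    if (length(centers0) == 0) abort("no anchor events fully inside the trace")
  } else {
    bouts <- if (is.null(spec$state_constraint)) {
      tibble::tibble(start = 0, end = total)
    } else {
      state_bouts(hyp, spec$state_constraint)
    }
    bouts <- dplyr::filter(bouts, .data$end - .data$start >= spec$segment_len)
    if (nrow(bouts) == 0) abort("no eligible state bouts")
  }
  mu <- mean(trace); sigma <- sd(trace)
  withr::with_seed(sub_seed(spec$seed, paste0("segments-", anchor)), {
    purrr::map_dfr(seq_len(spec$n_iterations), function(it) {
      centers <- if (anchor == "random") {
        w <- bouts$end - bouts$start - spec$segment_len
        b <- sample.int(nrow(bouts), spec$n_samples, replace = TRUE,
                        prob = pmax(w, 1e-9))
        bouts$start[b] + half + runif(spec$n_samples, 0, pmax(w[b], 0))
      } else {
        sample(centers0, min(spec$n_samples, length(centers0)), replace = FALSE)
      }
      purrr::imap_dfr(centers, function(cc, id) {
        i0 <- max(1L, round((cc - half) * fs) + 1L)
        i1 <- min(length(trace), i0 + round(spec$segment_len * fs) - 1L)
        seg <- trace[i0:i1]
        z <- if (sigma > 0) abs(mean(seg) - mu) / sigma else 0
        excl <- z > spec$zscore_exclusion ||
          any(abs(seg) > spec$amplitude_exclusion)
        tibble::tibble(iteration = it, id = id, start = (i0 - 1) / fs,
                       end = i1 / fs, excluded = excl,
                       segment = list(if (excl) NULL else seg))
      })
    })
  })
}

#' Aligned-versus-shuffled paired comparison
#'
#' Reduces aligned and shuffled segment sets to one metric value per
#' subject, pairs them, and applies a one-sided exact Wilcoxon signed-rank
#' test (alternative: aligned exceeds shuffled). Inputs carry a `subject`
#' column and either a list-column `segment` (reduced by `metric_fn`) or a
#' precomputed `value` column.
#'
#' @param aligned,shuffled data frames as described above.
#' @param metric_fn function applied to each segment (ignored when a
#'   `value` column is present).
#' @param sided test sidedness (default one).
#' @return a list: `per_subject` tibble (subject, aligned, shuffled, diff)
#'   and `test` (an `exact_test`; degenerate all-zero differences give a
#'   flagged trivial result with a warning).
#' @export
aligned_vs_shuffled <- function(aligned, shuffled, metric_fn = mean,
                                sided = "one") {
  per_cond <- function(d) {
    stopifnot("subject" %in% names(d))
    if (!"value" %in% names(d)) {
      stopifnot("segment" %in% names(d))
      d$value <- purrr::map_dbl(d$segment, function(s)
        if (is.null(s)) NA_real_ else metric_fn(s))
    }
    d |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                       .groups = "drop")
  }
  a <- per_cond(aligned); s <- per_cond(shuffled)
  if (!setequal(a$subject, s$subject)) abort("subject sets differ")
  m <- dplyr::inner_join(a, s, by = "subject", suffix = c("_aligned", "_shuffled"))
  d <- m$value_aligned - m$value_shuffled
  test <- if (all(d == 0)) {
    warn("all paired differences are zero: degenerate comparison")
    new_exact_test(NA_real_, 1, sided, "degenerate", length(d))
  } else {
    wilcoxon_exact(d, sided = sided)
  }
  list(per_subject = tibble::tibble(subject = m$subject,
                                    aligned = m$value_aligned,
                                    shuffled = m$value_shuffled, diff = d),
       test = test)
}

#' Detected-versus-shuffled normalized power spectra
#'
#' Averaged periodograms of equally long detected and shuffled segments,
#' each normalized to its total power and expressed in decibels. Returns the
#' spectra and a summary of the event-band peak in each condition.
#'
#' @param det_segments,shuf_segments lists of equal-length numeric segments.
#' @param fs sampling rate, Hz.
#' @param band event band for the peak summary, Hz (default 9-16).
#' @return a list: `spectra` tibble (`freq`, `db_det`, `db_shuf`) and
#'   `band_peak` tibble (condition, peak_db, peak_freq).
#' @export
spindle_psd_contrast <- function(det_segments, shuf_segments, fs,
                                 band = c(9, 16)) {
  det_segments <- purrr::compact(det_segments)
  shuf_segments <- purrr::compact(shuf_segments)
  lens <- vapply(c(det_segments, shuf_segments), length, integer(1))
  if (length(unique(lens)) != 1) abort("segments have differing lengths")
  n <- lens[1]
  mean_psd <- function(segs) {
    p <- vapply(segs, function(s) {
      sp <- (Mod(fft(s - mean(s)))^2)[seq_len(floor(n / 2))]
      sp / sum(sp)
    }, numeric(floor(n / 2)))
    rowMeans(p)
  }
  freqs <- (seq_len(floor(n / 2)) - 1) * fs / n
  db_det <- 10 * log10(mean_psd(det_segments))
  db_shuf <- 10 * log10(mean_psd(shuf_segments))
  in_band <- freqs >= band[1] & freqs <= band[2]
  list(
    spectra = tibble::tibble(freq = freqs, db_det = db_det, db_shuf = db_shuf),
    band_peak = tibble::tibble(
      condition = c("det", "shuff"),
      peak_db = c(max(db_det[in_band]), max(db_shuf[in_band])),
      peak_freq = c(freqs[in_band][which.max(db_det[in_band])],
                    freqs[in_band][which.max(db_shuf[in_band])]))
  )
}

#' Simulate 1 Hz-entrained NREM blocks
#'
#' Builds a long synthetic NREM EEG stream of `n_blocks` 10 s blocks in
#' which every stimulation cycle (pulse of `pulse_width` light-on at
#' `pulse_rate`) is followed by a spindle burst in the light-off part of the
#' cycle, emulating stimulation-entrained spindle activity. Used to verify
#' entrainment periodicity in the relative-sigma-power cross-correlogram.
#'
#' @param n_blocks number of 10 s blocks (default 100).
#' @param pulse_rate stimulation rate, Hz (default 1).
#' @param pulse_width light-on time, s (default 0.2).
#' @param config a [synth_config()] providing EEG rate, background and
#'   spindle amplitude conventions.
#' @param burst_latency spindle onset after each pulse onset, s.
#' @param burst_dur spindle burst duration, s.
#' @param seed integer seed.
#' @return a list: `eeg` (numeric), `fs`, `pulse_onsets` (s).
#' @export
simulate_entrained_nrem <- function(n_blocks = 100, pulse_rate = 1,
                                    pulse_width = 0.2,
                                    config = synth_config(),
                                    burst_latency = 0.25, burst_dur = 0.6,
                                    seed = 1) {
  fs <- config$eeg_rate
  dur <- n_blocks * 10
  n <- round(dur * fs)
  cycle <- 1 / pulse_rate
  onsets <- seq(0, dur - cycle, by = cycle)
  withr::with_seed(sub_seed(seed, "entrained"), {
    eeg <- pink_noise(n, config$noise_exponent) * config$eeg_rms
    tt <- (seq_len(n) - 1) / fs
    eeg <- eeg + 1.2 * config$eeg_rms * sin(2 * pi * 2 * tt)
    for (o in onsets) {
      f <- runif(1, config$spindle_freq_range[1], config$spindle_freq_range[2])
      burst <- spindle_burst(fs, burst_dur, f,
                             config$spindle_amp_snr * config$eeg_rms,
                             phase = runif(1, 0, 2 * pi))
      eeg <- add_kernel_at(eeg, fs, o + burst_latency, burst, 1)
    }
    list(eeg = eeg, fs = fs, pulse_onsets = onsets)
  })
}
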