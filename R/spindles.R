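# Three-threshold sleep spindle detector with per-event characterization.
#
# A single EEG trace is band-pass filtered to a broad band (1-30 Hz) and to
# the event band (sigma 9-16 Hz; mu 8-12 Hz). Three decision series are
# computed -- relative sigma power (STFT), moving broad-vs-sigma Pearson
# correlation, and moving sigma RMS -- thresholded (0.2 / 0.65 / mean + 1.5
# SD), summed into a decision vector, smoothed (soft threshold), and
# contiguous stretches where at least two of three thresholds are exceeded
# become events after gap merging and duration filtering.

#' Spindle detection parameters
#'
#' Defaults follow the validated three-threshold detection scheme: relative
#' sigma power from a 2 s / 0.2 s STFT thresholded at 0.2; broad-vs-sigma
#' moving Pearson correlation (0.3 s / 0.1 s) thresholded at 0.65; moving
#' sigma RMS (0.3 s / 0.1 s) thresholded at mean + 1.5 SD; decision vector
#' smoothed over 0.1 s; two of three votes required; events closer than
#' 0.1 s merged; durations outside 0.5-2 s removed; event peaks counted with
#' a 60 ms minimum separation.
#'
#' @param broad_band,event_band Hz pairs: broadband and event band.
#' @param relpow_window,relpow_step,relpow_thresh STFT window/step (s) and
#'   relative-power threshold (fraction, in `[0, 1]`).
#' @param corr_window,corr_step,corr_thresh moving-correlation window/step
#'   (s) and threshold (in `[-1, 1]`).
#' @param rms_window,rms_step,rms_sd_mult moving-RMS window/step (s) and the
#'   SD multiplier in the RMS threshold.
#' @param soft_window decision-vector smoothing window, s.
#' @param min_votes votes (of 3) required after smoothing.
#' @param merge_gap events spaced less than this (s) are merged.
#' @param min_dur,max_dur admissible event duration bounds, s.
#' @param peak_min_interval minimum spacing between counted peaks, s.
#' @return a validated `spindle_params` list.
#' @export
spindle_params <- function(broad_band = c(1, 30), event_band = c(9, 16),
                           relpow_window = 2.0, relpow_step = 0.2,
                           relpow_thresh = 0.2,
                           corr_window = 0.3, corr_step = 0.1,
                           corr_thresh = 0.65,
                           rms_window = 0.3, rms_step = 0.1,
                           rms_sd_mult = 1.5,
                           soft_window = 0.1, min_votes = 2,
                           merge_gap = 0.1, min_dur = 0.5, max_dur = 2.0,
                           peak_min_interval = 0.060) {
  stopifnot(min_dur > 0, min_dur < max_dur,
            relpow_window > 0, corr_window > 0, rms_window > 0,
            relpow_thresh >= 0, relpow_thresh <= 1,
            corr_thresh >= -1, corr_thresh <= 1,
            length(broad_band) == 2, length(event_band) == 2)
  structure(as.list(environment()), class = "spindle_params")
}

# Index matrix of sliding frames: one column per frame.
frame_index <- function(n, wlen, wstep) {
  starts <- frame_starts(n, wlen, wstep)
  if (length(starts) == 0) abort("trace shorter than analysis window")
  list(idx = outer(seq_len(wlen) - 1L, starts, "+"),
       centers = (starts - 1L + (wlen - 1L) / 2))
}

# Short-time relative band power of `x` (already broad-band filtered).
stft_relpow <- function(x, fs, params) {
  wlen <- round(params$relpow_window * fs)
  wstep <- max(1L, round(params$relpow_step * fs))
  fr <- frame_index(length(x), wlen, wstep)
  w <- hann_window(wlen)
  frames <- matrix(x[fr$idx], nrow = wlen) * w
  spec <- Mod(stats::mvfft(frames))^2
  freqs <- (seq_len(wlen) - 1) * fs / wlen
  band_i <- freqs >= params$event_band[1] & freqs <= params$event_band[2]
  broad_i <- freqs >= params$broad_band[1] & freqs <= params$broad_band[2]
  broad_pow <- colSums(spec[broad_i, , drop = FALSE])
  rel <- ifelse(broad_pow > 0,
                colSums(spec[band_i, , drop = FALSE]) / broad_pow, 0)
  list(t = fr$centers / fs, v = rel)
}

moving_corr <- function(x, y, fs, window, step) {
  wlen <- round(window * fs)
  wstep <- max(1L, round(step * fs))
  fr <- frame_index(length(x), wlen, wstep)
  xm <- matrix(x[fr$idx], nrow = wlen)
  ym <- matrix(y[fr$idx], nrow = wlen)
  mx <- colMeans(xm); my <- colMeans(ym)
  cxy <- colMeans(xm * ym) - mx * my
  vx <- colMeans(xm^2) - mx^2
  vy <- colMeans(ym^2) - my^2
  r <- ifelse(vx > 0 & vy > 0, cxy / sqrt(vx * vy), 0)
  list(t = fr$centers / fs, v = r, degenerate = any(vx <= 0 | vy <= 0))
}

moving_rms <- function(x, fs, window, step) {
  wlen <- round(window * fs)
  wstep <- max(1L, round(step * fs))
  fr <- frame_index(length(x), wlen, wstep)
  v <- sqrt(colMeans(matrix(x[fr$idx], nrow = wlen)^2))
  list(t = fr$centers / fs, v = v)
}

#' Spindle decision series
#'
#' Computes the three thresholded decision series on a common per-sample time
#' grid: relative event-band power (STFT of the broad-band signal), moving
#' Pearson correlation between the broad-band and event-band filtered
#' signals, and the moving RMS of the event-band signal, along with the data-
#' driven RMS threshold (mean + `rms_sd_mult` x SD of the RMS series). Frame
#' values are step-interpolated onto the sample grid (frames carry their
#' centre time), so no sub-window resolution is fabricated.
#'
#' @param eeg numeric EEG trace.
#' @param fs sampling rate, Hz.
#' @param params a [spindle_params()].
#' @return a tibble with columns `t`, `relpow`, `corr`, `rms`; attributes
#'   `rms_threshold` and `degenerate` (TRUE when a zero-variance window
#'   forced a correlation of 0, also signalled as a warning).
#' @export
decision_signals <- function(eeg, fs, params = spindle_params()) {
  stopifnot(is.numeric(eeg), all(is.finite(eeg)))
  if (length(eeg) < params$relpow_window * fs)
    abort("trace shorter than the relative-power window")
  broad <- bandpass(eeg, fs, params$broad_band)
  sigma <- bandpass(eeg, fs, params$event_band)
  rp <- stft_relpow(broad, fs, params)
  mc <- moving_corr(broad, sigma, fs, params$corr_window, params$corr_step)
  mr <- moving_rms(sigma, fs, params$rms_window, params$rms_step)
  if (isTRUE(mc$degenerate))
    warn("zero-variance window(s): correlation emitted as 0 there")
  rms_threshold <- mean(mr$v) + params$rms_sd_mult * sd(mr$v)
  tt <- (seq_along(eeg) - 1) / fs
  out <- tibble::tibble(
    t = tt,
    relpow = step_interp(rp$t, rp$v, tt),
    corr = step_interp(mc$t, mc$v, tt),
    rms = step_interp(mr$t, mr$v, tt)
  )
  attr(out, "rms_threshold") <- rms_threshold
  attr(out, "degenerate") <- isTRUE(mc$degenerate)
  out
}

# Runs of TRUE in a logical vector as half-open sample-index intervals.
logical_runs <- function(flag) {
  r <- rle(as.vector(flag))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble::tibble(first = starts[r$values], last = ends[r$values])
}

#' Detect candidate spindle events
#'
#' Applies the two-of-three vote rule to the decision series: per-sample
#' votes (strict threshold exceedance) are summed, smoothed with a
#' `soft_window` moving average, and contiguous runs with smoothed votes at
#' or above `min_votes` become candidates. Candidates spaced less than
#' `merge_gap` apart are merged, then candidates shorter than `min_dur` or
#' longer than `max_dur` are removed.
#'
#' @inheritParams decision_signals
#' @return a tibble of half-open event intervals: `start`, `end` (s).
#' @export
detect_events <- function(eeg, fs, params = spindle_params()) {
  ds <- decision_signals(eeg, fs, params)
  votes <- (ds$relpow > params$relpow_thresh) +
    (ds$corr > params$corr_thresh) +
    (ds$rms > attr(ds, "rms_threshold"))
  k <- max(1L, round(params$soft_window * fs))
  smoothed <- as.numeric(stats::filter(votes, rep(1 / k, k), sides = 2))
  smoothed[is.na(smoothed)] <- 0
  runs <- logical_runs(smoothed >= params$min_votes)
  if (nrow(runs) == 0)
    return(tibble::tibble(start = numeric(0), end = numeric(0)))
  ev <- tibble::tibble(start = (runs$first - 1) / fs, end = runs$last / fs)
  # merge events separated by less than merge_gap
  merged <- ev[1, ]
  for (i in seq_len(nrow(ev))[-1]) {
    if (ev$start[i] - merged$end[nrow(merged)] < params$merge_gap) {
      merged$end[nrow(merged)] <- ev$end[i]
    } else {
      merged <- dplyr::bind_rows(merged, ev[i, ])
    }
  }
  dur <- merged$end - merged$start
  merged[dur >= params$min_dur & dur <= params$max_dur, ]
}

# Features of one event given pre-filtered traces and the relpow series.
event_features_one <- function(broad, sigma, relpow, fs, start, end, params) {
  i0 <- max(1L, floor(start * fs) + 1L)
  i1 <- min(length(broad), ceiling(end * fs))
  bseg <- broad[i0:i1]; sseg <- sigma[i0:i1]
  if (sd(bseg) == 0) {
    return(tibble::tibble(
      start = start, end = end, duration = end - start,
      rms_amp = NA_real_, abs_power = NA_real_, rel_power = NA_real_,
      p2p_amplitude = NA_real_, frequency = NA_real_,
      oscillations = NA_integer_, symmetry = NA_real_, degenerate = TRUE))
  }
  env <- Mod(analytic_signal(sseg))
  pk <- pracma::findpeaks(bseg,
                          minpeakdistance = max(1L, round(params$peak_min_interval * fs)))
  tibble::tibble(
    start = start, end = end, duration = end - start,
    rms_amp = sqrt(mean(bseg^2)),
    abs_power = median(log10(env^2 + .Machine$double.eps)),
    rel_power = median(relpow[i0:i1]),
    p2p_amplitude = max(bseg) - min(bseg),
    frequency = median(instantaneous_frequency(sseg, fs)),
    oscillations = if (is.null(pk)) 0L else nrow(pk),
    symmetry = (which.max(env) - 1) / (length(env) - 1),
    degenerate = FALSE
  )
}

#' Characterize a detected event
#'
#' Computes the eight per-event features over a half-open `[start, end)`
#' interval: RMS amplitude of the broad-band waveform; median log10 event-
#' band power from the analytic-signal envelope; median per-point relative
#' event-band power; peak-to-peak amplitude (max minus min); median
#' instantaneous frequency of the event-band analytic signal; oscillation
#' count (waveform peaks at least `peak_min_interval` apart); and symmetry,
#' the normalized position (0 start, 1 end) of the envelope maximum, the
#' event's most prominent point.
#'
#' @inheritParams decision_signals
#' @param interval numeric length-2, event start and end in seconds.
#' @return a one-row tibble of event features; constant segments return NA
#'   features with `degenerate = TRUE`.
#' @export
event_features <- function(eeg, fs, interval, params = spindle_params()) {
  stopifnot(length(interval) == 2, interval[1] < interval[2],
            interval[1] >= 0, interval[2] <= length(eeg) / fs)
  broad <- bandpass(eeg, fs, params$broad_band)
  sigma <- bandpass(eeg, fs, params$event_band)
  rp <- stft_relpow(broad, fs, params)
  tt <- (seq_along(eeg) - 1) / fs
  relpow <- step_interp(rp$t, rp$v, tt)
  event_features_one(broad, sigma, relpow, fs, interval[1], interval[2], params)
}

#' Detect and characterize spindle or mu events
#'
#' Full detection pipeline: band selection ("spindle" 9-16 Hz or "mu"
#' 8-12 Hz, all other parameters shared), three-threshold event detection,
#' and per-event featurization. The RMS threshold statistics are computed
#' over the trace passed in, so restrict the input to the state of interest
#' (e.g. NREM) when that is the analysis intent.
#'
#' @inheritParams decision_signals
#' @param band `"spindle"` (9-16 Hz) or `"mu"` (8-12 Hz).
#' @return a tibble with one row per detected event and the eight feature
#'   columns of [event_features()].
#' @export
detect_spindles <- function(eeg, fs, params = spindle_params(),
                            band = c("spindle", "mu")) {
  band <- match.arg(band)
  params$event_band <- switch(band, spindle = c(9, 16), mu = c(8, 12))
  ev <- detect_events(eeg, fs, params)
  if (nrow(ev) == 0) {
    return(tibble::tibble(
      start = numeric(0), end = numeric(0), duration = numeric(0),
      rms_amp = numeric(0), abs_power = numeric(0), rel_power = numeric(0),
      p2p_amplitude = numeric(0), frequency = numeric(0),
      oscillations = integer(0), symmetry = numeric(0),
      degenerate = logical(0)))
  }
  broad <- bandpass(eeg, fs, params$broad_band)
  sigma <- bandpass(eeg, fs, params$event_band)
  rp <- stft_relpow(broad, fs, params)
  tt <- (seq_along(eeg) - 1) / fs
  relpow <- step_interp(rp$t, rp$v, tt)
  purrr::pmap_dfr(ev, function(start, end) {
    event_features_one(broad, sigma, relpow, fs, start, end, params)
  })
}

#' Write an event table as CSV
#'
#' Columns are named Start, End, Duration, Amplitude, RMS, AbsPower,
#' RelPower, Frequency, Oscillations, Symmetry.
#'
#' @param events event tibble from [detect_spindles()].
#' @param path output file path.
#' @export
write_events_csv <- function(events, path) {
  out <- data.frame(
    Start = events$start, End = events$end, Duration = events$duration,
    Amplitude = events$p2p_amplitude, RMS = events$rms_amp,
    AbsPower = events$abs_power, RelPower = events$rel_power,
    Frequency = events$frequency, Oscillations = events$oscillations,
    Symmetry = events$symmetry
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
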