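# Photometry and EMG preprocessing plus event-locked and spectral analyses.

#' Compute delta-F/F from a two-wavelength photometry recording
#'
#' The reference (isosbestic-like) channel is mapped onto the signal channel
#' by an ordinary least-squares affine fit over the whole session; the fitted
#' trace is the baseline f0 and `dff = (f - f0) / f0` pointwise. Artifact
#' components common to both channels are removed up to the fit error. The
#' result is invariant to affine rescaling of the reference channel.
#'
#' @param photo a data frame with columns `signal` and `reference` (and
#'   optionally `t`), or a numeric signal vector (then `reference` must be
#'   supplied).
#' @param reference numeric reference trace when `photo` is a vector.
#' @return a tibble with columns `t` (if supplied), `f`, `f_ref`, `f0`,
#'   `dff`.
#' @examples
#' ref <- 100 + sin(seq(0, 10, by = 0.01))
#' compute_dff(tibble::tibble(signal = 2 * ref + 5, reference = ref))
#' @export
compute_dff <- function(photo, reference = NULL) {
  if (is.data.frame(photo)) {
    f <- photo$signal; f_ref <- photo$reference
    t <- if ("t" %in% names(photo)) photo$t else NULL
  } else {
    f <- photo; f_ref <- reference; t <- NULL
  }
  stopifnot(length(f) == length(f_ref), all(is.finite(f)), all(is.finite(f_ref)))
  if (mean(f_ref) <= 0) abort("reference channel must have positive mean")
  if (var(f_ref) == 0) abort("reference channel has zero variance; fit is degenerate")
  fit <- stats::lm.fit(cbind(1, f_ref), f)
  f0 <- as.numeric(cbind(1, f_ref) %*% fit$coefficients)
  if (any(f0 <= 0)) abort("fitted baseline is non-positive; dff undefined")
  out <- tibble::tibble(f = f, f_ref = f_ref, f0 = f0, dff = (f - f0) / f0)
  if (!is.null(t)) out <- dplyr::bind_cols(tibble::tibble(t = t), out)
  out
}

#' Half-wave rectify and low-pass filter
#'
#' `max(x, 0)` followed by a zero-phase low-pass at `cutoff`.
#'
#' @param x numeric trace.
#' @param fs sampling rate, Hz.
#' @param cutoff low-pass corner, Hz (must be below Nyquist).
#' @return filtered numeric vector.
#' @export
rectify_lowpass <- function(x, fs, cutoff) {
  if (cutoff <= 0 || cutoff >= fs / 2) abort("cutoff must be in (0, fs/2)")
  bandpass(pmax(x, 0), fs, c(0, cutoff))
}

#' Label movement epochs from an EMG trace
#'
#' The EMG is rectified and smoothed into an envelope (0.5 s moving
#' average); the movement threshold is `median(envelope) + 7 x
#' MAD(envelope)`, with the MAD taken raw by default (no 1.4826 consistency
#' factor, matching its use as a robust SD surrogate; set
#' `mad_constant = 1.4826` to apply it). A 10 s epoch is labelled movement
#' when any envelope sample within it exceeds the threshold.
#'
#' @param emg numeric EMG trace.
#' @param fs sampling rate, Hz.
#' @param epoch_len epoch length, s (default 10).
#' @param mad_mult threshold multiplier on the MAD (default 7).
#' @param smooth_window envelope moving-average window, s (default 0.5).
#' @param mad_constant MAD consistency constant (default 1: raw MAD).
#' @return a tibble with one row per epoch: `epoch`, `t0`, `movement`;
#'   attributes `threshold` and `degenerate` (constant EMG gives MAD 0 and a
#'   flagged degenerate threshold).
#' @export
movement_labels <- function(emg, fs, epoch_len = 10, mad_mult = 7,
                            smooth_window = 0.5, mad_constant = 1) {
  stopifnot(all(is.finite(emg)))
  k <- max(1L, round(smooth_window * fs))
  env <- as.numeric(stats::filter(abs(emg), rep(1 / k, k), sides = 2))
  env[is.na(env)] <- 0
  med <- median(env)
  m <- mad(env, constant = mad_constant)
  degenerate <- m == 0
  threshold <- med + mad_mult * m
  n_epochs <- floor(length(emg) / (epoch_len * fs))
  epoch_of <- pmin(n_epochs, floor((seq_along(env) - 1) / (epoch_len * fs)) + 1L)
  exceed <- env > threshold & !degenerate
  moved <- vapply(seq_len(n_epochs),
                  function(e) any(exceed[epoch_of == e]), logical(1))
  out <- tibble::tibble(epoch = seq_len(n_epochs),
                        t0 = (seq_len(n_epochs) - 1) * epoch_len,
                        movement = moved)
  attr(out, "threshold") <- threshold
  attr(out, "degenerate") <- degenerate
  if (degenerate) warn("constant EMG: degenerate movement threshold (MAD = 0)")
  out
}

#' Rolling Pearson correlation
#'
#' Centred moving-window Pearson r between two equally long traces.
#' Zero-variance windows emit 0 (flagged via the `degenerate` attribute).
#'
#' @param x,y numeric traces of equal length.
#' @param fs sampling rate, Hz.
#' @param window window length, s (default 5).
#' @return a tibble `t`, `r` on the window-centre grid (one value per
#'   sample step of `window/50`, i.e. a dense rolling series).
#' @export
rolling_pearson <- function(x, y, fs, window = 5) {
  stopifnot(length(x) == length(y))
  if (length(x) < window * fs) abort("traces shorter than the window")
  mc <- moving_corr(x, y, fs, window, step = 1 / fs)
  out <- tibble::tibble(t = mc$t, r = mc$v)
  attr(out, "degenerate") <- isTRUE(mc$degenerate)
  out
}

#' Relative band power trace
#'
#' Short-time fraction of band power over broad power (default sigma 9-16 Hz
#' over 1-30 Hz, 0.5 s window, 0.1 s step), values in `[0, 1]`, reported at
#' window-centre times.
#'
#' @param eeg numeric EEG trace.
#' @param fs sampling rate, Hz.
#' @param band,broad Hz pairs: numerator band and broadband reference.
#' @param window,step STFT window and step, s.
#' @return a tibble `t`, `relpow`.
#' @export
relative_band_power_trace <- function(eeg, fs, band = c(9, 16),
                                      broad = c(1, 30),
                                      window = 0.5, step = 0.1) {
  if (window < 2 / band[1])
    warn("window shorter than two cycles of the band's low corner")
  p <- spindle_params(broad_band = broad, event_band = band,
                      relpow_window = window, relpow_step = step)
  if (length(eeg) < window * fs) abort("trace shorter than the window")
  x <- bandpass(eeg, fs, broad)
  rp <- stft_relpow(x, fs, p)
  tibble::tibble(t = rp$t, relpow = rp$v)
}

#' Event-triggered average
#'
#' Aligns signal snippets to event times, averages them, and locates the
#' latency to the peak of the mean response within the analysis window.
#' Events whose window extends beyond the trace are dropped.
#'
#' @param signal numeric trace.
#' @param fs sampling rate, Hz.
#' @param event_times event onsets, s.
#' @param window length-2 numeric: analysis window relative to onset, s
#'   (default `c(0, 1)`).
#' @return an `event_triggered` list: `lags` (s), `mean_response`, `sem`,
#'   `latency_to_peak` (s; `NA` with `degenerate = TRUE` for a flat mean
#'   response), `n_events`.
#' @export
event_triggered <- function(signal, fs, event_times, window = c(0, 1)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  i_lo <- round(window[1] * fs); i_hi <- round(window[2] * fs)
  lags <- (i_lo:i_hi) / fs
  onsets <- round(event_times * fs) + 1L
  keep <- onsets + i_lo >= 1 & onsets + i_hi <= length(signal)
  onsets <- onsets[keep]
  if (length(onsets) == 0) abort("no events fully inside the trace")
  snips <- vapply(onsets, function(o) signal[(o + i_lo):(o + i_hi)],
                  numeric(length(lags)))
  m <- rowMeans(snips)
  sem <- apply(snips, 1, sd) / sqrt(length(onsets))
  degenerate <- max(m) - min(m) < .Machine$double.eps^0.5
  structure(
    list(lags = lags, mean_response = m, sem = sem,
         latency_to_peak = if (degenerate) NA_real_ else lags[which.max(m)],
         n_events = length(onsets), degenerate = degenerate),
    class = "event_triggered"
  )
}

#' @export
print.event_triggered <- function(x, ...) {
  cat(sprintf("<event_triggered> n = %d events, window [%g, %g] s\n",
              x$n_events, min(x$lags), max(x$lags)))
  cat(sprintf("  latency to peak: %s s\n",
              if (is.na(x$latency_to_peak)) "undefined (flat)"
              else format(x$latency_to_peak)))
  invisible(x)
}

#' @method tidy event_triggered
#' @export
tidy.event_triggered <- function(x, ...) {
  tibble::tibble(lag = x$lags, mean = x$mean_response, sem = x$sem)
}

#' @method glance event_triggered
#' @export
glance.event_triggered <- function(x, ...) {
  tibble::tibble(latency_to_peak = x$latency_to_peak, n_events = x$n_events,
                 peak = max(x$mean_response), degenerate = x$degenerate)
}

#' Cross-correlogram of a series against a pulse train
#'
#' Normalized cross-correlation between a regularly sampled series (e.g. the
#' relative sigma power trace) and the indicator train of pulse onsets, over
#' lags up to `max_lag`. Positive lags mean the series follows the pulses.
#'
#' @param series a tibble with columns `t` and a value column (first
#'   non-time column used), or a numeric vector with `fs` supplied via
#'   `series_fs`.
#' @param pulse_times pulse onset times, s.
#' @param max_lag maximum lag, s (default 10).
#' @param series_fs sampling rate of `series` when it is a bare vector.
#' @return a tibble `lag`, `r`.
#' @export
cross_correlogram <- function(series, pulse_times, max_lag = 10,
                              series_fs = NULL) {
  if (is.data.frame(series)) {
    tt <- series$t
    v <- series[[setdiff(names(series), "t")[1]]]
    dt <- median(diff(tt))
    t0 <- tt[1]
  } else {
    stopifnot(!is.null(series_fs))
    v <- series; dt <- 1 / series_fs; t0 <- 0
  }
  if (length(pulse_times) == 0) abort("no pulses supplied")
  n <- length(v)
  ind <- numeric(n)
  pi_idx <- round((pulse_times - t0) / dt) + 1L
  pi_idx <- pi_idx[pi_idx >= 1 & pi_idx <= n]
  if (length(pi_idx) == 0) abort("no pulses fall inside the series")
  ind[pi_idx] <- 1
  v <- v - mean(v); ind <- ind - mean(ind)
  max_k <- min(n - 2L, round(max_lag / dt))
  lags_k <- -max_k:max_k
  denom <- sqrt(sum(v^2) * sum(ind^2))
  r <- vapply(lags_k, function(k) {
    if (k >= 0) sum(v[(1 + k):n] * ind[1:(n - k)]) else
      sum(v[1:(n + k)] * ind[(1 - k):n])
  }, numeric(1)) / denom
  tibble::tibble(lag = lags_k * dt, r = r)
}

#' Count periodic peaks in a correlogram
#'
#' Local maxima of the correlation-vs-lag curve with positive correlation,
#' separated by at least `min_separation` seconds, restricted to
#' `lag_range`.
#'
#' @param xc tibble from [cross_correlogram()].
#' @param lag_range length-2 numeric, lags considered (default `c(0, 10)`).
#' @param min_separation minimum peak spacing, s (default 0.5).
#' @return integer peak count.
#' @export
count_correlogram_peaks <- function(xc, lag_range = c(0, 10),
                                    min_separation = 0.5) {
  sel <- xc$lag >= lag_range[1] & xc$lag <= lag_range[2]
  r <- xc$r[sel]
  dt <- median(diff(xc$lag))
  pk <- pracma::findpeaks(r, minpeakdistance = max(1L, round(min_separation / dt)),
                          minpeakheight = 0)
  if (is.null(pk)) 0L else nrow(pk)
}

#' Two-photon delta-F/F pipeline
#'
#' Mean-frame fluorescence pipeline for ex vivo imaging: background
#' subtraction, photobleach correction by fitting and dividing a single
#' decaying exponential (`a * exp(-t/tau) + c`, nonlinear least squares),
#' 5-point running-mean filtering, and delta-F/F against the pre-stimulus
#' baseline mean.
#'
#' @param trace numeric mean fluorescence per frame.
#' @param stim_onset stimulus onset, in frames; at least 20 pre-stimulus
#'   frames are required.
#' @param background scalar background level to subtract (default 0).
#' @return a tibble `frame`, `corrected`, `dff`.
#' @export
twophoton_dff <- function(trace, stim_onset, background = 0) {
  stopifnot(is.numeric(trace), stim_onset >= 21)
  x <- trace - background
  tt <- seq_along(x)
  fit_exp <- function(keep) {
    d <- data.frame(y = x[keep], t0 = tt[keep])
    tryCatch(
      stats::nls(y ~ a * exp(-t0 / tau) + c0, data = d,
                 start = list(a = max(x) - min(x) + .Machine$double.eps,
                              tau = length(x) / 2, c0 = min(x)),
                 control = stats::nls.control(maxiter = 200, warnOnly = FALSE,
                                              scaleOffset = 1)),
      error = function(e) abort(paste0("exponential photobleach fit failed: ",
                                       conditionMessage(e)))
    )
  }
  # two-pass fit: frames with strongly positive residuals (calcium
  # transients) are excluded from the second pass so activity does not bias
  # the bleach estimate
  fit <- fit_exp(rep(TRUE, length(x)))
  res <- x - stats::predict(fit, data.frame(t0 = tt))
  if (sd(res) > 0) {
    keep <- res < 2 * sd(res)
    if (sum(keep) >= 20 && any(!keep)) fit <- fit_exp(keep)
  }
  bleach <- as.numeric(stats::coef(fit)[["a"]] * exp(-tt / stats::coef(fit)[["tau"]]) +
                         stats::coef(fit)[["c0"]])
  if (any(bleach <= 0)) abort("fitted baseline is non-positive")
  corrected <- x / bleach
  sm <- as.numeric(stats::filter(corrected, rep(1 / 5, 5), sides = 2))
  sm[is.na(sm)] <- corrected[is.na(sm)]
  f0 <- mean(sm[seq_len(stim_onset - 1)])
  tibble::tibble(frame = tt, corrected = sm, dff = (sm - f0) / f0)
}
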