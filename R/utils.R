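# Internal numerical helpers shared across the signal-processing modules.

#' @importFrom rlang %||% abort warn
#' @importFrom stats fft approx median mad sd quantile qnorm rnorm runif rpois
#'   rbinom rexp rgeom var cor complete.cases setNames
NULL

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
}

#' Zero-phase band-pass filter
#'
#' Forward-backward application of a Butterworth band-pass, so event timing is
#' not shifted by filter phase delay.
#'
#' @param x numeric trace.
#' @param fs sampling rate in Hz.
#' @param band length-2 numeric, low and high corner in Hz. A low corner of 0
#'   gives a low-pass; a high corner at or above Nyquist gives a high-pass.
#' @param order filter order (default 3).
#' @return filtered numeric vector, same length as `x`.
#' @export
bandpass <- function(x, fs, band, order = 3) {
  stopifnot(length(band) == 2, band[1] < band[2], fs > 0)
  nyq <- fs / 2
  if (band[2] >= nyq && band[1] <= 0) return(x)
  if (band[1] <= 0) {
    bf <- signal::butter(order, band[2] / nyq, type = "low")
  } else if (band[2] >= nyq) {
    bf <- signal::butter(order, band[1] / nyq, type = "high")
  } else {
    bf <- signal::butter(order, band / nyq, type = "pass")
  }
  as.numeric(signal::filtfilt(bf, x))
}

# FFT-based analytic signal (one-sided spectrum doubling).
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Median instantaneous frequency (Hz) of a band-limited trace.
instantaneous_frequency <- function(x, fs) {
  ph <- Arg(analytic_signal(x))
  dph <- diff(ph)
  dph <- (dph + pi) %% (2 * pi) - pi  # unwrap step-wise
  dph * fs / (2 * pi)
}

# Start indices (1-based) of sliding frames of `wlen` samples every `wstep`.
frame_starts <- function(n, wlen, wstep) {
  if (n < wlen) return(integer(0))
  seq.int(1L, n - wlen + 1L, by = wstep)
}

# Apply `fun` over sliding frames; returns centre times (s) and values.
frame_apply <- function(x, fs, window, step, fun) {
  wlen <- max(2L, round(window * fs))
  wstep <- max(1L, round(step * fs))
  starts <- frame_starts(length(x), wlen, wstep)
  vals <- vapply(starts, function(s) fun(x[s:(s + wlen - 1L)]), numeric(1))
  list(t = (starts - 1L + (wlen - 1L) / 2) / fs, v = vals)
}

# Step (piecewise-constant) interpolation of frame values onto a sample grid.
step_interp <- function(t_frames, v_frames, t_out) {
  if (length(t_frames) == 1L) return(rep(v_frames, length(t_out)))
  approx(t_frames, v_frames, xout = t_out, method = "constant",
         rule = 2, f = 0.5)$y
}

# 1/f^alpha noise via spectral synthesis, unit RMS; draws from the current RNG.
# The positive-frequency half gets complex-Gaussian coefficients scaled by
# f^(-alpha/2); taking Re() of the inverse FFT enforces a real trace with the
# same power-law spectrum.
pink_noise <- function(n, exponent = 1) {
  nf <- floor(n / 2)
  amp <- seq_len(nf)^(-exponent / 2)
  spec <- complex(real = rnorm(nf), imaginary = rnorm(nf)) * amp
  full <- complex(length.out = n)
  full[2:(nf + 1)] <- spec
  x <- Re(fft(full, inverse = TRUE))
  x <- x - mean(x)
  x / sqrt(mean(x^2))
}

# Deterministic sub-stream seed from a session seed and a component name.
sub_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)) * 131)
  (as.integer(seed) %% 100000L) * 20011L + (h %% 19997L)
}

# Any-overlap of half-open intervals [s, e) with the epoch [t0, t0 + len).
interval_overlaps_epoch <- function(start, end, t0, len) {
  start < t0 + len & end > t0
}

# Fraction of [a1,a2) covered by overlap with [b1,b2).
interval_overlap_frac <- function(a1, a2, b1, b2) {
  ov <- pmax(0, pmin(a2, b2) - pmax(a1, b1))
  ov / (a2 - a1)
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a finite number in [%s, %s]", name, min, max))
  }
  invisible(x)
}
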