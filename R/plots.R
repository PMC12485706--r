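# ggplot2 visualisation helpers for the main result types.

#' Plot a hypnogram
#'
#' @param hyp hypnogram tibble (`t0`, `state`).
#' @return a ggplot object.
#' @export
plot_hypnogram <- function(hyp) {
  lev <- data.frame(state = STATES, y = c(3, 2, 1))
  d <- dplyr::left_join(as.data.frame(hyp), lev, by = "state")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t0 / 60, y = .data$y)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(breaks = 3:1, labels = STATES,
                                limits = c(0.5, 3.5)) +
    ggplot2::labs(x = "time (min)", y = NULL, title = "Hypnogram")
}

#' Plot an EEG stretch with detected events
#'
#' @param eeg numeric trace.
#' @param fs sampling rate, Hz.
#' @param events event tibble (`start`, `end`).
#' @param xlim optional time range, s.
#' @return a ggplot object.
#' @export
plot_spindles <- function(eeg, fs, events, xlim = NULL) {
  d <- data.frame(t = (seq_along(eeg) - 1) / fs, v = eeg)
  if (!is.null(xlim)) {
    d <- d[d$t >= xlim[1] & d$t <= xlim[2], ]
    events <- events[events$end >= xlim[1] & events$start <= xlim[2], ]
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$t, .data$v)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "EEG (V)")
  if (nrow(events) > 0) {
    p <- p + ggplot2::geom_rect(
      data = as.data.frame(events),
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.25)
  }
  p
}

#' @method autoplot event_triggered
#' @export
autoplot.event_triggered <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$lag, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$latency_to_peak,
                        linetype = "dashed") +
    ggplot2::labs(x = "lag (s)", y = "mean response",
                  title = sprintf("Event-triggered average (n = %d)",
                                  object$n_events))
}

#' @method autoplot lomo_decode
#' @export
autoplot.lomo_decode <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr,
                                           group = .data$subject)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_line(data = object$mean_roc,
                       ggplot2::aes(group = NULL), linewidth = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("LOMO ROC (mean AUC = %.2f)",
                                  object$mean_auc))
}

#' Plot a cross-correlogram
#'
#' @param xc tibble from [cross_correlogram()].
#' @return a ggplot object.
#' @export
plot_correlogram <- function(xc) {
  ggplot2::ggplot(xc, ggplot2::aes(.data$lag, .data$r)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "lag (s)", y = "correlation")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
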