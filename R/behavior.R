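# Go/no-go behavioural scoring: performance, d-prime, bias, disengagement
# truncation, and training-half deltas.
#
# A trial log is a tibble with one row per trial:
#   trial (integer), type ("go"/"nogo"), lick (logical: any lick inside the
#   response window), outcome ("hit"/"miss"/"false_alarm"/"correct_reject").
# `outcome` can be derived from `type` + `lick`; `score_trials()` recomputes
# it to keep the two consistent.

trial_outcome <- function(type, lick) {
  dplyr::case_when(
    type == "go" & lick ~ "hit",
    type == "go" & !lick ~ "miss",
    type == "nogo" & lick ~ "false_alarm",
    TRUE ~ "correct_reject"
  )
}

#' Score a go/no-go trial log
#'
#' Tallies outcomes and computes performance, sensitivity (d') and response
#' bias. `performance` is (hits + correct rejections) / all trials. With `z`
#' the standard-normal quantile function, `dprime = z(H) - z(FA)` and
#' `bias = (z(H) + z(FA)) / 2`, where H and FA are the hit and false-alarm
#' rates. Extreme rates (0 or 1) are corrected to `1/(2N)` and `1 - 1/(2N)`
#' of the relevant trial count before the z transform, and the correction is
#' flagged in the output.
#'
#' @param trials a trial-log data frame with columns `type` ("go"/"nogo") and
#'   `lick` (logical).
#' @return a one-row tibble: `n_go`, `n_nogo`, `hit_rate`, `fa_rate`,
#'   `performance`, `dprime`, `bias`, `rate_corrected`.
#' @examples
#' log <- tibble::tibble(type = rep(c("go", "nogo"), each = 10),
#'                       lick = rep(c(TRUE, FALSE), each = 10))
#' score_trials(log)
#' @export
score_trials <- function(trials) {
  stopifnot(is.data.frame(trials), all(c("type", "lick") %in% names(trials)))
  type <- trials$type
  lick <- as.logical(trials$lick)
  n_go <- sum(type == "go"); n_nogo <- sum(type == "nogo")
  if (n_go == 0 || n_nogo == 0) abort("need at least one go and one no-go trial")
  outcome <- trial_outcome(type, lick)
  hits <- sum(outcome == "hit"); cr <- sum(outcome == "correct_reject")
  H <- hits / n_go; FA <- sum(outcome == "false_alarm") / n_nogo
  corrected <- FALSE
  if (H == 0) { H <- 1 / (2 * n_go); corrected <- TRUE }
  if (H == 1) { H <- 1 - 1 / (2 * n_go); corrected <- TRUE }
  if (FA == 0) { FA <- 1 / (2 * n_nogo); corrected <- TRUE }
  if (FA == 1) { FA <- 1 - 1 / (2 * n_nogo); corrected <- TRUE }
  tibble::tibble(
    n_go = n_go, n_nogo = n_nogo,
    hit_rate = H, fa_rate = FA,
    performance = (hits + cr) / (n_go + n_nogo),
    dprime = qnorm(H) - qnorm(FA),
    bias = (qnorm(H) + qnorm(FA)) / 2,
    rate_corrected = corrected
  )
}

#' Truncate a session at disengagement
#'
#' Scans the ordered trial log for the first run of 10 consecutive go trials
#' with no lick, with no licks on the no-go trials falling between the first
#' and the last go trial of the run (satiation rule used to terminate
#' sessions). All trials from the first go trial of that run onward are
#' dropped; logs with no such run are returned unchanged. Idempotent.
#'
#' @param trials a trial-log data frame with columns `type` and `lick`, in
#'   presentation order.
#' @param n_go_misses run length defining disengagement (default 10).
#' @return the (possibly truncated) trial log as a tibble.
#' @export
disengagement_cut <- function(trials, n_go_misses = 10) {
  stopifnot(is.data.frame(trials), all(c("type", "lick") %in% names(trials)))
  go_idx <- which(trials$type == "go")
  if (length(go_idx) < n_go_misses) return(tibble::as_tibble(trials))
  lick <- as.logical(trials$lick)
  for (s in seq_len(length(go_idx) - n_go_misses + 1)) {
    run <- go_idx[s:(s + n_go_misses - 1)]
    if (any(lick[run])) next
    between <- setdiff(seq(run[1], run[n_go_misses]), run)
    if (any(lick[between])) next
    return(tibble::as_tibble(trials[seq_len(run[1] - 1), , drop = FALSE]))
  }
  tibble::as_tibble(trials)
}

#' Training-half deltas of behavioural metrics
#'
#' Splits an ordered sequence of session metrics at the 4th session from the
#' last training day and returns, per metric, mean(second part) - mean(first
#' part). Used to quantify improvement across training.
#'
#' @param session_metrics a data frame with one row per session (in training
#'   order) and columns `performance`, `dprime`, `bias`.
#' @param split_from_end the split point, counted from the end (default 4:
#'   the last `split_from_end` sessions form the second part).
#' @return a one-row tibble: `delta_performance`, `delta_dprime`,
#'   `delta_bias`, `n_first`, `n_second`.
#' @export
delta_metrics <- function(session_metrics, split_from_end = 4) {
  stopifnot(is.data.frame(session_metrics))
  need <- c("performance", "dprime", "bias")
  stopifnot(all(need %in% names(session_metrics)))
  n <- nrow(session_metrics)
  if (n < split_from_end + 1) abort("need more sessions than the split length")
  first <- session_metrics[seq_len(n - split_from_end), , drop = FALSE]
  second <- session_metrics[(n - split_from_end + 1):n, , drop = FALSE]
  tibble::tibble(
    delta_performance = mean(second$performance) - mean(first$performance),
    delta_dprime = mean(second$dprime) - mean(first$dprime),
    delta_bias = mean(second$bias) - mean(first$bias),
    n_first = nrow(first), n_second = nrow(second)
  )
}

#' Simulate a learner on the go/no-go task
#'
#' Generates seeded session logs for a learner whose hit rate drifts up and
#' false-alarm rate drifts down across sessions at `learning_rate`, with a
#' `lapse` floor/ceiling and an initial lick bias. Trial outcomes are
#' Bernoulli draws; go and no-go trials are interleaved at random in equal
#' numbers.
#'
#' @param learning_rate per-session shift of H (up) and FA (down), in rate
#'   units per session.
#' @param lapse asymptotic error rate bounding H below `1 - lapse` and FA
#'   above `lapse`.
#' @param bias0 initial shared lick probability offset (positive: lick-prone).
#' @param n_sessions,trials_per_session session count and trials per session.
#' @param seed integer seed; identical seeds give identical logs.
#' @return a list of `n_sessions` trial-log tibbles (columns `trial`, `type`,
#'   `lick`, `outcome`).
#' @export
simulate_learner <- function(learning_rate = 0.03, lapse = 0.1, bias0 = 0,
                             n_sessions = 8, trials_per_session = 100,
                             seed = 1) {
  stopifnot(learning_rate >= 0, learning_rate <= 1, lapse >= 0, lapse <= 0.5)
  withr::with_seed(sub_seed(seed, "learner"), {
    purrr::map(seq_len(n_sessions), function(s) {
      H <- min(1 - lapse, 0.5 + bias0 + learning_rate * (s - 1))
      FA <- max(lapse, 0.5 + bias0 - learning_rate * (s - 1))
      n2 <- floor(trials_per_session / 2)
      type <- sample(rep(c("go", "nogo"), c(trials_per_session - n2, n2)))
      lick <- ifelse(type == "go",
                     rbinom(trials_per_session, 1, H),
                     rbinom(trials_per_session, 1, FA)) == 1
      tibble::tibble(trial = seq_len(trials_per_session), type = type,
                     lick = lick, outcome = trial_outcome(type, lick))
    })
  })
}
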