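# Epoch-level calcium feature extraction and leave-one-subject-out decoding
# of movement / spindle labels with shuffled-label baselines.

CALCIUM_FEATURES <- c("std", "mad", "iqr", "rms_dx", "pow_0.2_0.5")

#' Preprocess a calcium trace for decoding
#'
#' Zero-phase low-pass at 1 Hz followed by resampling to 50 Hz.
#'
#' @param dff numeric calcium (delta-F/F) trace.
#' @param fs sampling rate, Hz (must be at least 50).
#' @param target output rate, Hz (default 50).
#' @return numeric trace at `target` Hz.
#' @export
preprocess_calcium <- function(dff, fs, target = 50) {
  if (fs < target) abort("sampling rate below the 50 Hz target")
  x <- bandpass(dff, fs, c(0, 1))
  if (fs == target) return(x)
  t_in <- (seq_along(x) - 1) / fs
  t_out <- seq(0, t_in[length(t_in)], by = 1 / target)
  approx(t_in, x, xout = t_out)$y
}

#' Epoch-level calcium summary features
#'
#' Splits a 50 Hz trace into consecutive 10 s epochs and computes the five
#' summary statistics per epoch: standard deviation (`std`), median absolute
#' deviation (`mad`, unscaled), interquartile range (`iqr`), root mean
#' square of successive differences (`rms_dx`), and relative low-frequency
#' power `pow_0.2_0.5` (periodogram power in 0.2-0.5 Hz over total power in
#' 0.05-3 Hz). Constant epochs give zero spread features and a power ratio
#' of 0 with `degenerate = TRUE`.
#'
#' @param trace50 numeric trace (nominally 50 Hz).
#' @param fs sampling rate, Hz (default 50).
#' @param epoch_len epoch length, s (default 10).
#' @return a tibble with one row per complete epoch: `epoch`, `t0`, the five
#'   features, `degenerate`.
#' @export
epoch_features <- function(trace50, fs = 50, epoch_len = 10) {
  n_per <- round(epoch_len * fs)
  n_epochs <- floor(length(trace50) / n_per)
  if (n_epochs < 1) abort("trace shorter than one epoch")
  purrr::map_dfr(seq_len(n_epochs), function(e) {
    x <- trace50[((e - 1) * n_per + 1):(e * n_per)]
    degenerate <- sd(x) == 0
    pr <- if (degenerate) 0 else {
      spec <- Mod(fft(x - mean(x)))^2
      freqs <- (seq_along(x) - 1) * fs / length(x)
      num <- sum(spec[freqs >= 0.2 & freqs <= 0.5])
      den <- sum(spec[freqs >= 0.05 & freqs <= 3])
      if (den > 0) num / den else 0
    }
    tibble::tibble(
      epoch = e, t0 = (e - 1) * epoch_len,
      std = sd(x), mad = mad(x, constant = 1),
      iqr = stats::IQR(x),
      rms_dx = if (length(x) > 1) sqrt(mean(diff(x)^2)) else 0,
      `pow_0.2_0.5` = pr,
      degenerate = degenerate
    )
  })
}

#' Label epochs by interval overlap
#'
#' An epoch is positive iff any interval overlaps it under the half-open
#' `[t0, t0 + epoch_len)` convention.
#'
#' @param epochs a tibble with a `t0` column (e.g. from [epoch_features()]).
#' @param intervals a tibble with `start`, `end` columns, s.
#' @param epoch_len epoch length, s (default 10).
#' @return the `epochs` tibble with a logical `label` column added.
#' @export
label_epochs <- function(epochs, intervals, epoch_len = 10) {
  stopifnot(is.data.frame(epochs), "t0" %in% names(epochs))
  lab <- vapply(epochs$t0, function(t0) {
    nrow(intervals) > 0 &&
      any(interval_overlaps_epoch(intervals$start, intervals$end, t0, epoch_len))
  }, logical(1))
  dplyr::mutate(epochs, label = lab)
}

scale_train_test <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test, 2, mu), 2, sdv, "/"))
}

roc_on_grid <- function(labels, scores, grid = seq(0, 1, length.out = 101)) {
  r <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                 levels = c(FALSE, TRUE), direction = "<")
  fpr <- rev(1 - r$specificities)
  tpr <- rev(r$sensitivities)
  list(auc = as.numeric(pROC::auc(r)),
       tpr = approx(fpr, tpr, xout = grid, ties = max, rule = 2)$y,
       fpr = grid)
}

#' Leave-one-subject-out decoding with a shuffled-label baseline
#'
#' For each held-out subject: feature standardization is fit on the training
#' subjects only, an elastic-net-penalized logistic regression (mixing 0.5,
#' fixed penalty) is trained, and ROC/AUC are evaluated on the held-out
#' subject. Per-fold ROC curves are vertically averaged on a common 101-point
#' false-positive-rate grid; the reported mean AUC is the mean of per-fold
#' AUCs. The chance baseline repeats the identical procedure with labels
#' permuted within each subject (seeded). Folds whose test set contains a
#' single class are skipped with a warning.
#'
#' @param data a data frame with the feature columns, a logical/2-level
#'   `label` column and a `subject` column.
#' @param features feature column names (default the five calcium features).
#' @param seed integer seed for the within-subject label shuffle.
#' @param alpha elastic-net mixing (default 0.5).
#' @param lambda penalty strength; default `1/n_train` per fold, the
#'   unit-strength convention.
#' @param shuffled compute the shuffled-label baseline (default TRUE).
#' @return a `lomo_decode` object: `per_fold` (subject, n_test, auc,
#'   auc_shuffled), `roc` (subject, fpr, tpr), `mean_roc`, `mean_auc`,
#'   `mean_shuffled_auc`, `feature_weights`.
#' @export
lomo_decode <- function(data, features = CALCIUM_FEATURES, seed = 1,
                        alpha = 0.5, lambda = NULL, shuffled = TRUE) {
  stopifnot(is.data.frame(data), all(features %in% names(data)),
            all(c("label", "subject") %in% names(data)))
  y <- as.logical(data$label)
  subj <- as.character(data$subject)
  if (length(unique(subj)) < 2) abort("need at least 2 subjects")
  if (length(unique(y)) < 2) abort("both classes must be present overall")
  X <- as.matrix(data[features])

  y_shuf <- withr::with_seed(sub_seed(seed, "label-shuffle"), {
    ys <- y
    for (s in unique(subj)) {
      i <- which(subj == s)
      ys[i] <- ys[sample(i)]
    }
    ys
  })

  fit_fold <- function(train_i, test_i, yy) {
    if (length(unique(yy[test_i])) < 2 || length(unique(yy[train_i])) < 2)
      return(NULL)
    sc <- scale_train_test(X[train_i, , drop = FALSE], X[test_i, , drop = FALSE])
    lam <- lambda %||% (1 / length(train_i))
    fit <- glmnet::glmnet(sc$train, factor(yy[train_i]), family = "binomial",
                          alpha = alpha, lambda = lam, standardize = FALSE)
    scores <- as.numeric(stats::predict(fit, sc$test, type = "response"))
    list(roc = roc_on_grid(yy[test_i], scores),
         coefs = as.numeric(stats::coef(fit))[-1])
  }

  subjects <- unique(subj)
  folds <- purrr::map(subjects, function(s) {
    test_i <- which(subj == s); train_i <- which(subj != s)
    main <- fit_fold(train_i, test_i, y)
    if (is.null(main)) {
      warn(sprintf("fold '%s' skipped: single-class train or test set", s))
      return(NULL)
    }
    shuf <- if (shuffled) fit_fold(train_i, test_i, y_shuf) else NULL
    list(subject = s, n_test = length(test_i), main = main, shuf = shuf)
  })
  folds <- purrr::compact(folds)
  if (length(folds) == 0) abort("all folds skipped")

  per_fold <- purrr::map_dfr(folds, function(f) {
    tibble::tibble(subject = f$subject, n_test = f$n_test,
                   auc = f$main$roc$auc,
                   auc_shuffled = if (is.null(f$shuf)) NA_real_
                                  else f$shuf$roc$auc)
  })
  roc <- purrr::map_dfr(folds, function(f) {
    tibble::tibble(subject = f$subject, fpr = f$main$roc$fpr,
                   tpr = f$main$roc$tpr)
  })
  mean_roc <- roc |>
    dplyr::group_by(.data$fpr) |>
    dplyr::summarise(tpr = mean(.data$tpr), .groups = "drop")
  weights <- purrr::map(folds, function(f) f$main$coefs)
  fold_weights <- purrr::map_dfr(folds, function(f) {
    tibble::tibble(subject = f$subject, feature = features,
                   weight = f$main$coefs)
  })
  feature_weights <- tibble::tibble(
    feature = features,
    weight = rowMeans(do.call(cbind, weights))
  )
  structure(
    list(per_fold = per_fold, roc = roc, mean_roc = mean_roc,
         mean_auc = mean(per_fold$auc),
         mean_shuffled_auc = mean(per_fold$auc_shuffled),
         feature_weights = feature_weights, fold_weights = fold_weights,
         seed = seed),
    class = "lomo_decode"
  )
}

#' @export
print.lomo_decode <- function(x, ...) {
  cat(sprintf("<lomo_decode> %d folds, mean AUC = %.3f (shuffled %.3f)\n",
              nrow(x$per_fold), x$mean_auc, x$mean_shuffled_auc))
  invisible(x)
}

#' @method tidy lomo_decode
#' @export
tidy.lomo_decode <- function(x, ...) x$per_fold

#' @method glance lomo_decode
#' @export
glance.lomo_decode <- function(x, ...) {
  tibble::tibble(n_folds = nrow(x$per_fold), mean_auc = x$mean_auc,
                 mean_shuffled_auc = x$mean_shuffled_auc)
}
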