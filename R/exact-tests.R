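# Exact small-sample nonparametric tests.
#
# The exact paths enumerate the full permutation null (all 2^n sign
# assignments for the signed-rank test; all choose(n1+n2, n1) rank
# arrangements for Mann-Whitney) via dynamic-programming convolution of the
# null counting distribution, which is arithmetically identical to brute-force
# enumeration but runs in polynomial time. Ties fall back to a midrank normal
# approximation with a warning.

MAX_ENUM <- 1e7

new_exact_test <- function(statistic, p, sided, method, n_config, note = NULL) {
  structure(
    list(statistic = statistic, p = p, sided = sided, method = method,
         n_config = n_config, note = note),
    class = "exact_test"
  )
}

#' @export
print.exact_test <- function(x, ...) {
  cat(sprintf("Exact test (%s, %s-sided)\n", x$method, x$sided))
  cat(sprintf("  statistic = %g, p = %.6g\n", x$statistic, x$p))
  cat(sprintf("  n = %s\n", paste(x$n_config, collapse = " vs ")))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @method tidy exact_test
#' @export
tidy.exact_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p.value = x$p, sided = x$sided,
    method = x$method, n = paste(x$n_config, collapse = ",")
  )
}

# Counts of the signed-rank statistic W+ (0..n(n+1)/2) over all 2^n sign
# assignments: coefficients of prod_k (1 + x^k).
signed_rank_null_counts <- function(n) {
  counts <- 1
  for (k in seq_len(n)) {
    shifted <- c(numeric(k), counts)
    counts <- c(counts, numeric(k)) + shifted
  }
  counts  # index i holds count of W+ = i - 1
}

# Counts of the rank-sum of a size-m subset of ranks 1..N over all C(N, m)
# subsets (untied case), by DP over elements with a size dimension.
rank_sum_null_counts <- function(m, N) {
  maxs <- N * (N + 1) / 2
  # counts[s + 1, j + 1] = number of size-j subsets of 1..k with sum s
  counts <- matrix(0, nrow = maxs + 1, ncol = m + 1)
  counts[1, 1] <- 1
  for (k in seq_len(N)) {
    for (j in rev(seq_len(min(k, m)))) {
      src <- counts[, j]
      counts[(k + 1):(maxs + 1), j + 1] <-
        counts[(k + 1):(maxs + 1), j + 1] + src[1:(maxs + 1 - k)]
    }
  }
  counts[, m + 1]  # index i holds count of rank-sum = i - 1
}

#' Exact Wilcoxon signed-rank test
#'
#' One- or two-sided signed-rank test with the p-value computed by exact
#' enumeration of all `2^n` sign assignments (zeros dropped before ranking,
#' the classic convention, so the one-sided minimum attainable p equals
#' `1/2^n`). Tied absolute differences force a midrank normal approximation,
#' flagged in the result.
#'
#' @param diffs numeric vector of paired differences.
#' @param sided `"one"` (alternative: differences tend positive) or `"two"`.
#' @return an `exact_test` object with `statistic` (W+, the positive rank
#'   sum), `p`, `sided`, `method` and `n_config`.
#' @examples
#' wilcoxon_exact(c(0.3, 0.1, 0.7, 0.2), sided = "one")
#' @export
wilcoxon_exact <- function(diffs, sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(is.numeric(diffs), length(diffs) >= 1)
  d <- diffs[is.finite(diffs) & diffs != 0]
  if (length(d) == 0) abort("all differences are zero or non-finite")
  n <- length(d)
  r <- rank(abs(d))
  wpos <- sum(r[d > 0])
  tied <- anyDuplicated(abs(d)) > 0
  if (!tied && 2^n <= MAX_ENUM) {
    counts <- signed_rank_null_counts(n)
    total <- 2^n
    p_ge <- sum(counts[(wpos + 1):length(counts)]) / total
    p_le <- sum(counts[1:(wpos + 1)]) / total
    p <- if (sided == "one") p_ge else min(1, 2 * min(p_ge, p_le))
    return(new_exact_test(wpos, p, sided, "exact_enumeration", n))
  }
  # midrank normal approximation with tie correction
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (wpos - mu - 0.5) / sqrt(sigma2)
  p_ge <- stats::pnorm(z, lower.tail = FALSE)
  z2 <- (wpos - mu + 0.5) / sqrt(sigma2)
  p_le <- stats::pnorm(z2)
  p <- if (sided == "one") p_ge else min(1, 2 * min(p_ge, p_le))
  if (tied) warn("tied |differences|: falling back to normal approximation")
  new_exact_test(wpos, p, sided, "normal_approx", n,
                 note = if (tied) "ties" else "large n")
}

#' Exact Mann-Whitney U test
#'
#' Two-sample rank test with the p-value computed by exact enumeration of all
#' `choose(n1+n2, n1)` equally likely rank arrangements, so that under
#' complete separation (every `x` above every `y`) the one-sided p equals
#' `1/choose(n1+n2, n1)`. Cross-group ties force a midrank normal
#' approximation, flagged in the result.
#'
#' @param x,y numeric samples.
#' @param sided `"one"` (alternative: `x` tends larger than `y`) or `"two"`.
#' @return an `exact_test` object; `statistic` is U for the `x` sample.
#' @examples
#' mannwhitney_exact(c(5, 6, 7), c(1, 2), sided = "one")
#' @export
mannwhitney_exact <- function(x, y, sided = c("one", "two")) {
  sided <- match.arg(sided)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0) abort("empty group")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])            # rank sum of x
  u <- w - n1 * (n1 + 1) / 2          # U statistic for x
  tied <- anyDuplicated(c(x, y)) > 0
  if (!tied && choose(N, n1) <= MAX_ENUM) {
    counts <- rank_sum_null_counts(n1, N)
    total <- choose(N, n1)
    p_ge <- sum(counts[(w + 1):length(counts)]) / total
    p_le <- sum(counts[1:(w + 1)]) / total
    p <- if (sided == "one") p_ge else min(1, 2 * min(p_ge, p_le))
    return(new_exact_test(u, p, sided, "exact_enumeration", c(n1, n2)))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  sigma2 <- n1 * n2 / 12 *
    ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  p_ge <- stats::pnorm((u - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  p_le <- stats::pnorm((u - mu + 0.5) / sqrt(sigma2))
  p <- if (sided == "one") p_ge else min(1, 2 * min(p_ge, p_le))
  if (tied) warn("cross-group ties: falling back to normal approximation")
  new_exact_test(u, p, sided, "normal_approx", c(n1, n2),
                 note = if (tied) "ties" else "large n")
}

#' Kruskal-Wallis omnibus with Dunn post hoc comparisons
#'
#' Omnibus Kruskal-Wallis H (chi-square reference) across three or more
#' groups, followed by pairwise Dunn z tests with tie correction. Dunn
#' p-values are reported unadjusted by default; `p_adjust` applies a stepwise
#' multiplicity correction.
#'
#' @param data a data frame with one observation per row.
#' @param value,group column names (strings) of the response and the grouping
#'   factor.
#' @param p_adjust a `stats::p.adjust` method for the pairwise p-values,
#'   default `"none"`.
#' @return a list with `omnibus` (tibble: statistic, df, p.value) and
#'   `pairwise` (tibble: group1, group2, z, p.value, p.adjusted).
#' @export
kruskal_dunn <- function(data, value = "value", group = "group",
                         p_adjust = "none") {
  stopifnot(is.data.frame(data), value %in% names(data), group %in% names(data))
  v <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 3) abort("Kruskal-Wallis omnibus requires at least 3 groups")
  ns <- table(g)
  if (any(ns == 0)) abort("empty group")
  kw <- stats::kruskal.test(v, g)
  N <- length(v)
  r <- rank(v)
  rbar <- tapply(r, g, mean)
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  combs <- utils::combn(levels(g), 2)
  pw <- purrr::map_dfr(seq_len(ncol(combs)), function(k) {
    a <- combs[1, k]; b <- combs[2, k]
    se <- sqrt(s2 * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    tibble::tibble(group1 = a, group2 = b, z = z,
                   p.value = 2 * stats::pnorm(-abs(z)))
  })
  pw$p.adjusted <- stats::p.adjust(pw$p.value, method = p_adjust)
  list(
    omnibus = tibble::tibble(statistic = unname(kw$statistic),
                             df = unname(kw$parameter),
                             p.value = kw$p.value),
    pairwise = pw
  )
}
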