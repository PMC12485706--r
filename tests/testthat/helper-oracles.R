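# Brute-force enumeration oracles for the exact tests: literal expansion
# of every sign pattern / rank subset, independent of the package's
# dynamic-programming implementation.

# Oracle: one-sided signed-rank tail by explicit enumeration of all 2^n sign
# patterns.
wilcoxon_bruteforce_p <- function(diffs, sided = "one") {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  if (sided == "one") p_ge else min(1, 2 * min(p_ge, p_le))
}

# Oracle: one-sided Mann-Whitney tail by explicit enumeration of all
# choose(N, n1) rank subsets.
mannwhitney_bruteforce_p <- function(x, y, sided = "one") {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  subsets <- utils::combn(N, n1)
  w_all <- colSums(matrix(seq_len(N)[subsets], nrow = n1))
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  if (sided == "one") p_ge else min(1, 2 * min(p_ge, p_le))
}

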