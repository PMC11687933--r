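# Independent oracles used across the suite. These re-derive the reference
# quantities by brute force (enumeration, closed form) and never call the
# code paths they check.

# Two-sided Fisher exact p by direct hypergeometric point-probability
# enumeration over the conditional 2x2 tables with fixed margins.
fisher_oracle <- function(a, b, c, d, alternative = "two.sided") {
  m1 <- a + b   # row 1 total (cases)
  k <- a + c    # column 1 total (positives)
  n <- a + b + c + d
  support <- max(0, k - (n - m1)):min(k, m1)
  probs <- vapply(support, function(x) {
    exp(lchoose(m1, x) + lchoose(n - m1, k - x) - lchoose(n, k))
  }, numeric(1))
  p_obs <- probs[support == a]
  if (alternative == "greater") {
    sum(probs[support >= a])
  } else {
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
}

# Exact two-sided Mann-Whitney p by enumeration of all group labelings
# (requires no ties; n1 + n2 small).
mw_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  u_of <- function(idx) {
    yv <- pooled[-idx]
    sum(rank(pooled)[-idx]) - length(yv) * (length(yv) + 1) / 2
  }
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, u_of)
  u_obs <- u_of(seq_len(n1))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Exact two-sided Wilcoxon signed-rank p by enumeration of all 2^n sign
# assignments of the absolute differences (no zero or tied magnitudes).
wsr_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

# Direct Benjamini-Hochberg step-up.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# Exact binomial 99% confidence bounds for an observed proportion.
binom99 <- function(p0, n) {
  c(
    lower = stats::qbinom(0.005, n, p0) / n,
    upper = stats::qbinom(0.995, n, p0) / n
  )
}

# Small cohort config used where full study sizes are unnecessary.
small_config <- function(seed = 1L, ...) {
  synth_config(
    seed = seed,
    n_t21 = 30L, n_d21 = 20L,
    antigen_params = default_small_antigens(),
    ...
  )
}

default_small_antigens <- function(n = 20) {
  tibble::tibble(
    antigen = sprintf("AG%03d", seq_len(n)),
    bg_loc = 0, bg_scale = 0.3,
    pos_prob_t21 = 0.05, pos_prob_d21 = 0.05,
    pos_shift = 3
  )
}
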