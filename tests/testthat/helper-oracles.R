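# Independent oracles used to check the package's statistics.  These stay
# deliberately brute-force and share no code with the implementation.

# BH step-up by hand: sort ascending, p(i)*m/i, running minima from the
# largest rank down, cap at 1, restore input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# BY: BH with the harmonic-sum correction multiplied in before the
# monotone pass.
by_oracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ranked <- p[o] * m * cm / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Two-sided Fisher exact p by exhaustive enumeration of all tables with
# the observed margins: sum the probabilities of tables no more probable
# than the observed (with the conventional 1e-7 relative tolerance for
# floating-point ties).
fisher_two_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(ks, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Upper-tail Fisher p (overrepresentation): direct tail sum.
fisher_greater_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  ks <- a:min(r1, c1)
  sum(dhyper(ks, r1, r2, c1))
}

# Hypergeometric upper tail by direct combinatorial summation.
hyper_tail_oracle <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Welch two-sample t by hand: statistic, Welch-Satterthwaite df, two-sided
# p from the t CDF.
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t_stat <- (mean(y) - mean(x)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

# One-sample t by hand.
onesample_t_oracle <- function(x) {
  n <- length(x)
  t_stat <- mean(x) / (sd(x) / sqrt(n))
  list(t = t_stat, df = n - 1, p = 2 * pt(-abs(t_stat), n - 1))
}

# Pearson r by direct formula evaluation.
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
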