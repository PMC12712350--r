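# Independent oracles used across the suite. These deliberately use only
# base R primitives and brute-force enumeration, never the package's own
# code paths.

# two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins (probability-ordering definition, with
# the conventional 1 + 1e-7 relative slack when comparing likelihoods)
fisher_oracle <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  support <- lo:hi
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Wilcoxon rank-sum p by enumeration of all rank
# assignments (tie-free data only): p = min(1, 2 * min tail)
wilcox_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  ranks <- seq_len(n1 + n2)
  ws <- apply(sets, 2, function(s) sum(ranks[s])) - n1 * (n1 + 1) / 2
  lower <- mean(ws <= w_obs)
  upper <- mean(ws >= w_obs)
  min(1, 2 * min(lower, upper))
}

# hand-applied Benjamini-Hochberg step-up rule
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# textbook Pearson chi-square statistic sum((O-E)^2 / E)
chisq_oracle <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# log-Wald ROR interval computed directly from the formula
ror_oracle <- function(a, b, c, d) {
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(ror = ror, lo = exp(log(ror) - 1.96 * se), hi = exp(log(ror) + 1.96 * se))
}
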