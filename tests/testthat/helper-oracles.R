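# Independent small-n oracles used to pin expected values.

# two-sided Mann-Whitney p by exhaustive enumeration of group assignments
# (tie-free data), using the same two-sided convention as the exact
# distribution: double the attained tail, capped at 1
oracle_rank_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  assignments <- utils::combn(n1 + n2, n1)
  w_all <- apply(assignments, 2L, function(s) sum(r[s]) - n1 * (n1 + 1) / 2)
  p <- if (w_obs > n1 * n2 / 2) 2 * mean(w_all >= w_obs) else
    2 * mean(w_all <= w_obs)
  min(1, p)
}

# two-sided Fisher exact p by hypergeometric enumeration, point-probability
# method (all tables with the observed margins whose probability does not
# exceed the observed table's)
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m1 <- a + b; m2 <- c_ + d; k <- a + c_
  support <- max(0, k - m2):min(k, m1)
  probs <- stats::dhyper(support, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg by the textbook recipe: p * m / rank, then running
# minimum from the largest p down
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), alpha)
  g / sum(g)
}
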