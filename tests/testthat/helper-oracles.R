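# Independent brute-force oracles for the exact tests and BH adjustment.
# These deliberately use direct factorial/step-up arithmetic, not the
# package's code paths.

# two-sided binomial p by explicit enumeration of the outcome masses
oracle_binom_p <- function(x, n, p0) {
  d <- exp(lchoose(n, 0:n) + (0:n) * log(p0) + (n - 0:n) * log1p(-p0))
  min(1, sum(d[d <= d[x + 1] * (1 + 1e-7)]))
}

# two-tailed Fisher p by explicit enumeration of all tables with the
# observed margins, probabilities from log-factorials
oracle_fisher_p <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; c1 <- a + c
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  k <- lo:hi
  probs <- exp(lchoose(r1, k) + lchoose(n - r1, c1 - k) - lchoose(n, c1))
  min(1, sum(probs[probs <= probs[a - lo + 1] * (1 + 1e-7)]))
}

# Benjamini-Hochberg by the direct step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}
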