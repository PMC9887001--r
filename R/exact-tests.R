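#' Two-sided exact binomial p-value
#'
#' Exact two-sided binomial test p-value by the minimum-likelihood rule: the
#' p-value is the total probability, under `Binomial(n, p0)`, of all outcomes
#' whose point probability does not exceed that of the observed count. At
#' `p0 = 0.5` this coincides (by symmetry) with doubling the smaller tail,
#' capped at 1. Vectorized over `x`, `n` and `p0`.
#'
#' This is the test used throughout the package for allele-specific expression
#' (paternal vs maternal read counts under a balanced null) and for the pooled
#' rate-ratio differential-expression test (null success probability equal to
#' the library-size share of one group).
#'
#' @param x Number of successes (e.g. paternal reads), non-negative integer.
#' @param n Number of trials (total informative reads), `n >= 1`.
#' @param p0 Null success probability in (0, 1). Default 0.5.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' exact_binom_p(12, 12)            # 2 * 0.5^12
#' exact_binom_p(30, 50)            # two-sided, balanced null
#' exact_binom_p(20, 30, p0 = 2/3)  # unbalanced null
#' @export
exact_binom_p <- function(x, n, p0 = 0.5) {
  m <- max(length(x), length(n), length(p0))
  x <- rep_len(as.numeric(x), m)
  n <- rep_len(as.numeric(n), m)
  p0 <- rep_len(as.numeric(p0), m)
  if (any(n < 1 | x < 0 | x > n)) {
    stop("require 0 <= x <= n and n >= 1", call. = FALSE)
  }
  if (any(p0 <= 0 | p0 >= 1)) stop("p0 must be in (0, 1)", call. = FALSE)
  # relative tolerance guards ties against floating-point noise (same
  # convention as stats::binom.test)
  rel <- 1 + 1e-7
  vapply(seq_len(m), function(i) {
    d <- stats::dbinom(0:n[i], n[i], p0[i])
    min(1, sum(d[d <= d[x[i] + 1] * rel]))
  }, numeric(1))
}

#' Two-tailed Fisher exact p-value for 2x2 count tables
#'
#' Exact two-tailed p-value for the table `[m_a, u_a; m_b, u_b]` by
#' enumeration of the conditional hypergeometric distribution: all tables with
#' the observed margins whose probability does not exceed the observed table's
#' probability contribute to p. Vectorized over the four count vectors.
#'
#' Used for per-CpG differential methylation between two bisulfite samples,
#' where the table rows are (methylated, unmethylated) read counts.
#'
#' @param m_a,u_a First sample's success/failure counts (e.g. methylated and
#'   unmethylated reads).
#' @param m_b,u_b Second sample's counts.
#' @return Numeric vector of two-tailed p-values in (0, 1].
#' @examples
#' fisher_exact_p(10, 0, 0, 10)  # 2 / choose(20, 10)
#' fisher_exact_p(4, 1, 1, 4)    # 52 / 252
#' @export
fisher_exact_p <- function(m_a, u_a, m_b, u_b) {
  m <- max(length(m_a), length(u_a), length(m_b), length(u_b))
  m_a <- rep_len(as.numeric(m_a), m)
  u_a <- rep_len(as.numeric(u_a), m)
  m_b <- rep_len(as.numeric(m_b), m)
  u_b <- rep_len(as.numeric(u_b), m)
  if (any(c(m_a, u_a, m_b, u_b) < 0)) stop("counts must be >= 0", call. = FALSE)
  rel <- 1 + 1e-7
  vapply(seq_len(m), function(i) {
    k <- m_a[i] + m_b[i]              # total successes (first column margin)
    na <- m_a[i] + u_a[i]             # row A total
    nb <- m_b[i] + u_b[i]             # row B total
    if (na + nb == 0) return(NA_real_)
    lo <- max(0, k - nb)
    hi <- min(k, na)
    d <- stats::dhyper(lo:hi, na, nb, k)
    min(1, sum(d[d <= d[m_a[i] - lo + 1] * rel]))
  }, numeric(1))
}
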