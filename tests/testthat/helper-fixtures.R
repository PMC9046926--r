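# Shared fixture builders; everything is generated in code at test time.

tinyParams <- function(...) {
  simParams(nGenes = 200L, nPerCell = 5L, seed = 7L, ...)
}

# Brute-force BH step-up oracle: suffix minima of p_(j) * m / j.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  pmin(adj, 1)[order(o)]
}

# Exhaustive hypergeometric upper tail via binomial coefficients.
hyperOracle <- function(k, N, m, n) {
  ks <- seq(max(0, n - (N - m)), min(m, n))
  pmf <- choose(m, ks) * choose(N - m, n - ks) / choose(N, n)
  sum(pmf[ks >= k])
}
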