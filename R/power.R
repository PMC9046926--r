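# Two-sample t-test power arithmetic: the false-negative-rate side of DEG
# calling. With FDR controlled at 5% but power rarely above 80%, false
# negatives outnumber false positives several-fold, which is what turns
# "significant in one group but not the other" into an artifact generator.

#' Power of the two-sided two-sample t-test
#'
#' Computed from the noncentral t distribution with `df = 2n - 2` and
#' noncentrality `d * sqrt(n / 2)` (equal group sizes, pooled variance).
#'
#' @param nPerGroup samples per group (numeric, may be fractional; >= 2).
#' @param d Cohen's d effect size (> 0; `d = 0` returns `alpha`).
#' @param alpha two-sided type I error rate, default 0.05.
#' @return Power in `[0, 1]`, vectorised over `nPerGroup` and `d`.
#' @examples
#' ttestPower(26, d = 0.8)  # just above 0.80
#' @export
ttestPower <- function(nPerGroup, d, alpha = 0.05) {
  if (any(nPerGroup < 2)) stop("nPerGroup must be >= 2")
  if (any(d < 0)) stop("d must be >= 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  df <- 2 * nPerGroup - 2
  ncp <- d * sqrt(nPerGroup / 2)
  tcrit <- qt(1 - alpha / 2, df)
  pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    pt(-tcrit, df, ncp = ncp, lower.tail = TRUE)
}

#' Required per-group sample size for a target power
#'
#' Solves `power(n) = target` by root finding on the noncentral t power
#' function and reports both the fractional solution and the smallest
#' integer `n` whose power reaches the target.
#'
#' @param d Cohen's d effect size (> 0).
#' @param alpha two-sided type I error rate, default 0.05.
#' @param power target power in `(0, 1)`, default 0.8.
#' @return List with `n_fractional` and `n_integer`.
#' @examples
#' requiredN(d = 0.8)$n_integer  # 26
#' @export
requiredN <- function(d, alpha = 0.05, power = 0.8) {
  if (d <= 0) stop("d must be > 0")
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  if (power <= alpha) {
    warning("target power does not exceed alpha; returning minimum n = 2")
    return(list(n_fractional = 2, n_integer = 2L))
  }
  f <- function(n) ttestPower(n, d, alpha) - power
  hi <- 4
  while (f(hi) < 0 && hi < 1e8) hi <- hi * 2
  if (f(hi) < 0) stop("required sample size search did not bracket a root")
  nFrac <- if (f(2) >= 0) 2 else uniroot(f, c(2, hi), tol = 1e-9)$root
  nInt <- max(2L, as.integer(ceiling(nFrac - 1e-9)))
  while (ttestPower(nInt, d, alpha) < power) nInt <- nInt + 1L
  list(n_fractional = nFrac, n_integer = nInt)
}

#' False negative rate implied by a power
#' @param power power in `[0, 1]`.
#' @return `1 - power`.
#' @examples
#' fnrFromPower(0.8)  # 0.2
#' @export
fnrFromPower <- function(power) {
  if (any(power < 0 | power > 1)) stop("power must lie in [0, 1]")
  1 - power
}
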