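#' Two-sample t-test (Student or Welch)
#'
#' The kernel used by every differential comparison in the package. The
#' default is Student's pooled-variance statistic with `nA + nB - 2` degrees
#' of freedom, matching the two-tailed Student's t-test reported for
#' proximity and stress comparisons; Welch's unequal-variance form with
#' Satterthwaite degrees of freedom is available via `equalVar = FALSE`.
#' The p-value is always two-sided. The estimate is `mean(a) - mean(b)`, so
#' on log2 intensities it is the log2 fold change.
#'
#' @param a,b numeric vectors with at least two finite values each; `NA`s
#'   are dropped.
#' @param equalVar pool the variances (Student) or not (Welch).
#' @return list with `estimate`, `tStat`, `p`, `df`, `nA`, `nB`.
#' @examples
#' twoSampleTTest(c(5.1, 4.9, 5.3, 5.0), c(4.1, 4.0, 4.2, 3.9))
#' @export
twoSampleTTest <- function(a, b, equalVar = TRUE) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs >= 2 observed values")
  res <- rowTTest(matrix(a, 1), matrix(b, 1), equalVar = equalVar)
  if (!is.na(res$reason[1]))
    stop(sprintf("undefined t statistic: %s", res$reason[1]))
  list(estimate = res$estimate[1], tStat = res$t[1], p = res$p[1],
       df = res$df[1], nA = res$nA[1], nB = res$nB[1])
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Converts p-values to FDR q-values by the step-up rule with monotonicity
#' enforcement: sorted q's are `min(1, cummin(m/i * p_(i)))` taken from the
#' largest p downwards, returned in the input order. `NA` p-values propagate
#' as `NA` and do not count toward `m`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return q-values, same length and order as `p`.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))
#' @export
bhAdjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pp <- p[ok]
  if (any(pp < 0 | pp > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pp)
  if (m == 0)
    return(q)
  o <- order(pp, decreasing = TRUE)
  q[ok] <- pmin(1, cummin(m / (m:1) * pp[o]))[order(o)]
  q
}

#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items from a
#' universe of `N` that contains `K` successes. Computed by summing the pmf
#' in log space (`lchoose`) with a max-shift, so it is stable for large
#' universes. This is the one-sided over-representation p-value used by
#' [ora()].
#'
#' @param k observed overlap (vectorized).
#' @param K successes in the universe (set size).
#' @param n draws (selection size).
#' @param N universe size.
#' @return `P(X >= k)`, same length as `k`.
#' @examples
#' hypergeometricTail(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeometricTail <- function(k, K, n, N) {
  if (K > N || n > N)
    stop("K and n must not exceed N")
  if (any(k < 0) || any(k > pmin(K, n)))
    stop("k must satisfy 0 <= k <= min(K, n)")
  vapply(k, function(k1) {
    if (k1 <= 0)
      return(1)
    j <- k1:min(K, n)
    lp <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
    mx <- max(lp)
    min(1, exp(mx) * sum(exp(lp - mx)))
  }, numeric(1))
}
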