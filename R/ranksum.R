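#' Two-sided Wilcoxon-Mann-Whitney rank-sum test
#'
#' Statistic is the rank sum W of the first group in the pooled ranking
#' (midranks for ties). The p-value is computed by exact enumeration of all
#' `choose(m+n, m)` group assignments of the observed (possibly tied) values
#' when both groups have at most `exactMax` observations, and otherwise by
#' the normal approximation with tie correction and continuity correction.
#' The two-sided exact p is `min(1, 2*min(P(W <= w), P(W >= w)))`.
#'
#' @param x,y numeric observation vectors of the two groups
#' @param exactMax exact enumeration is used when `length(x)` and
#'   `length(y)` are both at most this (default 8)
#' @return list with elements `statistic` (W) and `p.value`
#' @examples
#' rankSumTest(c(10, 11, 12), c(0, 0, 0))$p.value  # 2/20
#' @export
rankSumTest <- function(x, y, exactMax = 8L) {
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L) stop("both groups must be nonempty")
  N <- m + n
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  eps <- 1e-9
  if (m <= exactMax && n <= exactMax) {
    idx <- combn(N, m)
    Wd <- colSums(matrix(r[idx], nrow = m))
    p <- min(1, 2 * min(mean(Wd <= W + eps), mean(Wd >= W - eps)))
  } else {
    mu <- m * (N + 1) / 2
    ties <- table(r)
    sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(statistic = W, p.value = 1))
    d <- W - mu
    z <- (d - sign(d) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(statistic = W, p.value = p)
}
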