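#' Wilcoxon signed-rank test
#'
#' Paired two-sided signed-rank test. Zero differences are dropped;
#' ranks of the absolute differences are tie-averaged; the statistic is
#' `W+`, the rank sum of the positive differences. For `n <= 25`
#' retained pairs the p-value is exact — computed from the full null
#' distribution of `W+` over all `2^n` sign assignments (evaluated by
#' subset-sum convolution, which is identical to full enumeration) — as
#' `P(|W+ - mu| >= |w - mu|)` with `mu = S/2`, `S` the total rank sum.
#' Above `n = 25` a normal approximation with tie-corrected variance
#' `sum(r_i^2)/4` is used.
#'
#' @param x numeric vector (or precomputed differences if `y` is NULL).
#' @param y optional paired numeric vector; differences are `x - y`.
#' @param alternative only `"two.sided"` is implemented.
#' @return List with `statistic` (W+), `p.value`, `n` (pairs retained),
#'   and `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = "two.sided") {
  alternative <- match.arg(alternative, "two.sided")
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stop("x and y must have equal length")
    x - y
  }
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; p = 1")
    return(list(statistic = 0, p.value = 1, n = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25) {
    p <- wsr_exact_p(r, w)
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    p <- min(1, 2 * pnorm(-abs(w - mu) / sigma))
    method <- "normal"
  }
  list(statistic = w, p.value = p, n = as.integer(n), method = method)
}

# Exact two-sided p for W+ given the (tie-averaged) ranks. Doubling the
# ranks makes them integers; the null distribution of the doubled W+ is
# the distribution of subset sums with each rank included with
# probability 1/2, obtained by convolution.
wsr_exact_p <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  probs <- numeric(total + 1)
  probs[1] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), probs[seq_len(total + 1 - ri)])
    probs <- (probs + shifted) / 2
  }
  mu <- total / 2
  dev <- abs(round(2 * w) - mu)
  sums <- 0:total
  sum(probs[abs(sums - mu) >= dev - 1e-9])
}
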