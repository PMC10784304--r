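#' Friedman rank test for repeated measures
#'
#' Within-row tie-averaged ranks;
#' `Q = [12 / (n k (k+1))] * sum(R_j^2) - 3 n (k+1)`, divided by the
#' standard tie-correction factor `1 - sum(t^3 - t) / (n k (k^2 - 1))`.
#' The p-value comes either from the chi-squared `(k-1)` approximation
#' or, for small tables, from the exact permutation distribution
#' (all `(k!)^n` independent within-row rank permutations, evaluated by
#' convolution over column rank sums — identical to full enumeration).
#'
#' @param x numeric matrix, rows = subjects, columns = conditions.
#' @param method `"auto"` (exact when feasible, i.e. small `n` and `k`),
#'   `"exact"`, or `"chisq"`.
#' @return List with `statistic` (Q), `p.value`, `df`, `method`.
#' @export
friedman_rank_test <- function(x, method = c("auto", "exact", "chisq")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need >= 2 rows and >= 2 columns")
  ranks <- t(apply(x, 1, rank))
  Rj <- colSums(ranks)
  Q0 <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  ties <- sum(apply(x, 1, function(row) {
    tb <- table(row)
    sum(tb^3 - tb)
  }))
  corr <- 1 - ties / (n * k * (k^2 - 1))
  if (corr <= 0) {
    warning("all rows constant; Friedman test degenerate")
    return(list(statistic = 0, p.value = 1, df = k - 1,
                method = "degenerate"))
  }
  Q <- Q0 / corr
  exact_ok <- k <= 4 && n <= 12
  use_exact <- method == "exact" || (method == "auto" && exact_ok)
  if (method == "exact" && !exact_ok)
    stop("exact method limited to k <= 4 and n <= 12")
  if (use_exact) {
    p <- friedman_exact_p(ranks)
    meth <- "exact"
  } else {
    p <- pchisq(Q, df = k - 1, lower.tail = FALSE)
    meth <- "chisq"
  }
  list(statistic = Q, p.value = p, df = k - 1, method = meth)
}

# Exact permutation p-value: under the null every within-row permutation
# of that row's (tie-averaged) ranks is equally likely and rows are
# independent. Because the tie structure of each row is fixed, the
# tie-corrected Q is a monotone function of T = sum_j (R_j - mean)^2, so
# P(Q >= q_obs) = P(T >= t_obs). The distribution of the column-sum
# vector is accumulated row by row over doubled (integer) ranks.
friedman_exact_p <- function(ranks) {
  n <- nrow(ranks); k <- ncol(ranks)
  r2 <- round(2 * ranks)                    # doubled ranks are integers
  B <- 2 * k * n + 1                        # column sums live in [0, 2kn]
  L <- B^(k - 1)
  # per-row distinct permutation patterns, encoded as index shifts of
  # the first k-1 column sums
  row_shifts <- lapply(seq_len(n), function(i) {
    perms <- permutations_of(r2[i, ])
    shifts <- perms[, seq_len(k - 1), drop = FALSE] %*% B^(0:(k - 2))
    as.numeric(shifts)
  })
  v <- numeric(L); v[1] <- 1
  for (i in seq_len(n)) {
    sh <- row_shifts[[i]]
    w <- 1 / length(sh)
    nv <- numeric(L)
    for (s in sh) {
      if (s + 1 <= L)
        nv[(s + 1):L] <- nv[(s + 1):L] + v[seq_len(L - s)] * w
    }
    v <- nv
  }
  nz <- which(v > 0)
  idx0 <- nz - 1
  sums2 <- matrix(0, length(nz), k)          # doubled column sums
  rem <- idx0
  for (j in seq_len(k - 1)) {
    sums2[, j] <- rem %% B
    rem <- rem %/% B
  }
  total2 <- sum(r2)                          # = n * k * (k + 1) (no ties)
  sums2[, k] <- total2 - rowSums(sums2[, seq_len(k - 1), drop = FALSE])
  mean2 <- total2 / k
  Tvals <- rowSums((sums2 - mean2)^2)
  Robs2 <- colSums(r2)
  t_obs <- sum((Robs2 - mean2)^2)
  sum(v[nz][Tvals >= t_obs - 1e-9])
}

# all distinct permutations of a (possibly tied) small vector
permutations_of <- function(v) {
  k <- length(v)
  if (k == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (u in unique(v)) {
    i <- which(v == u)[1]
    sub <- permutations_of(v[-i])
    out <- rbind(out, cbind(u, sub))
  }
  unname(out)
}
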