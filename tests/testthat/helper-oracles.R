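# Independent brute-force oracles: plain double loops over the printed
# relationship-matrix formulas, no reuse of package kernel code.

oracleGBPseudoDiploid <- function(X, p) {
  n <- nrow(X); M <- ncol(X)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j == k) {
      acc <- 0
      for (i in seq_len(M))
        acc <- acc + (X[j, i]^2 - (1 + 2 * p[i]) * X[j, i] + 2 * p[i]^2) /
          (2 * p[i] * (1 - p[i]))
      K[j, k] <- 1 + acc / M
    } else {
      acc <- 0
      for (i in seq_len(M))
        acc <- acc + (X[j, i] - 2 * p[i]) * (X[k, i] - 2 * p[i]) /
          (2 * p[i] * (1 - p[i]))
      K[j, k] <- acc / M
    }
  }
  K
}

oracleGBAdditive <- function(Xstd) {
  n <- nrow(Xstd); M <- ncol(Xstd)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    acc <- 0
    for (i in seq_len(M)) acc <- acc + Xstd[j, i] * Xstd[k, i]
    K[j, k] <- acc / M
  }
  K
}

oracleGBFull <- function(Xc, p) {
  keep <- p > 0 & p < 1
  Xc <- Xc[, keep, drop = FALSE]
  p <- p[keep]
  n <- nrow(Xc); M <- ncol(Xc)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j == k) {
      acc <- 0
      for (i in seq_len(M))
        acc <- acc + (Xc[j, i]^2 - 2 * p[i] * Xc[j, i] + p[i]^2) /
          (p[i] * (1 - p[i]))
      K[j, k] <- 1 + acc / M
    } else {
      acc <- 0
      for (i in seq_len(M))
        acc <- acc + (Xc[j, i] - p[i]) * (Xc[k, i] - p[i]) /
          (p[i] * (1 - p[i]))
      K[j, k] <- acc / M
    }
  }
  K
}

oracleDist2 <- function(X) {
  n <- nrow(X)
  D2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D2[i, j] <- sum((X[i, ] - X[j, ])^2)
  D2
}

# closed-form GLS intercept + BLUP random effect for
# y = mu 1 + g + e, g ~ N(0, s2g K), e ~ N(0, s2e I), flat prior on mu
oracleBLUP <- function(y, K, s2g, s2e) {
  n <- length(y)
  V <- s2g * K + s2e * diag(n)
  Vi <- solve(V)
  one <- rep(1, n)
  mu <- drop(crossprod(one, Vi %*% y) / crossprod(one, Vi %*% one))
  list(mu = mu, g = drop(s2g * K %*% Vi %*% (y - mu * one)))
}

# dosage matrix guaranteed polymorphic at every marker (for kernel toys)
polymorphicDosage <- function(n, m, seed) {
  set.seed(seed)
  repeat {
    X <- matrix(rbinom(n * m, 4L, runif(m, 0.2, 0.8)[rep(seq_len(m),
                                                         each = n)]),
                n, m)
    p <- colMeans(X) / 4
    if (all(p > 0.05 & p < 0.95) && all(apply(X, 2, sd) > 0))
      return(tetraDosage(X))
  }
}
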