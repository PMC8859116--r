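test_that("all three GB constructions match brute-force double loops", {
  D <- polymorphicDosage(6, 20, seed = 101)
  fr <- alleleFreqs(D)

  KA <- kernelMatrix(gbPseudoDiploid(codePseudoDiploid(D), fr))
  oA <- oracleGBPseudoDiploid(codedValues(codePseudoDiploid(D)), alleleP(fr))
  expect_lt(max(abs(KA - oA)), 1e-12)

  XB <- codeAdditiveTetrasomic(D, standardize = TRUE)
  KB <- kernelMatrix(gbAdditive(XB))
  expect_lt(max(abs(KB - oracleGBAdditive(codedValues(XB)))), 1e-12)
  # population-variance standardization gives mean diagonal exactly 1
  expect_equal(mean(diag(KB)), 1)

  XC <- codeFullTetraploid(D)
  KC <- kernelMatrix(suppressMessages(gbFullTetraploid(XC)))
  oC <- oracleGBFull(codedValues(XC), XC@columnFreqs)
  expect_lt(max(abs(KC - oC)), 1e-12)
})

test_that("pseudo-diploid GB hand case: single marker at p = 0.5, both lines heterozygous", {
  # codes (1, 1) with p = 0.5: off-diagonal (1-1)(1-1)/0.5 = 0,
  # diagonal 1 + (1 - 2 + 0.5)/0.5 = 0
  D <- tetraDosage(matrix(c(2L, 2L, 0L, 4L), 2, 2))  # marker 2 fixes p = 0.5
  # build with explicit single-marker matrices instead: use the oracle
  X <- matrix(c(1, 1), 2, 1)
  K <- oracleGBPseudoDiploid(X, 0.5)
  expect_equal(K, matrix(0, 2, 2))
  # and the packaged version agrees on a matching 1-marker input
  fr <- new("AlleleFreqs", p = 0.5,
            classCounts = matrix(c(0L, 0L, 2L, 0L, 0L), 1))
  cm <- new("CodedMarkers", values = matrix(c(1, 1), 2, 1,
                                 dimnames = list(c("a", "b"), "m1")),
            coding = "A", standardized = FALSE, columnFreqs = 0.5)
  expect_equal(unname(kernelMatrix(gbPseudoDiploid(cm, fr))),
               matrix(0, 2, 2))
})

test_that("GB errors on unfiltered or unstandardized input", {
  D <- polymorphicDosage(6, 10, seed = 7)
  fr <- alleleFreqs(D)
  badfr <- new("AlleleFreqs", p = c(alleleP(fr)[-1], 0),
               classCounts = classCounts(fr))
  expect_error(gbPseudoDiploid(codePseudoDiploid(D), badfr),
               "filterMarkers")
  expect_error(gbAdditive(codeAdditiveTetrasomic(D, standardize = FALSE)),
               "standardized")
})

test_that("identical dosage rows give identical kernel rows", {
  D <- polymorphicDosage(5, 12, seed = 21)
  X <- dosageMatrix(D)
  X[2, ] <- X[1, ]
  X <- X[, apply(X, 2, sd) > 0, drop = FALSE]  # constant columns cannot be standardized
  D2 <- tetraDosage(X)
  K <- kernelMatrix(gbAdditive(codeAdditiveTetrasomic(D2)))
  expect_equal(K[1, -c(1, 2)], K[2, -c(1, 2)], ignore_attr = TRUE)
})

test_that("squared distances match the double-loop oracle and the 3-4-5 case", {
  expect_equal(squaredDistanceMatrix(rbind(c(0, 0), c(3, 4)))[1, 2], 25)
  set.seed(31)
  X <- matrix(rnorm(24), 6, 4)
  expect_equal(unname(squaredDistanceMatrix(X)), oracleDist2(X))
  expect_equal(diag(squaredDistanceMatrix(X)), rep(0, 6),
               ignore_attr = TRUE)
})

test_that("Gaussian kernel: hand-computed toy, unit diagonal, h-monotonicity", {
  X <- matrix(c(0, 1, 0, 0, 0, 2), 3, 2)  # rows (0,0), (1,0), (0,2)
  K <- gaussianKernel(X, h = 1)
  expect_equal(K@qMedian, 4)  # off-diagonal d2 = {1, 4, 5}
  expect_equal(kernelMatrix(K)[1, 2], exp(-1 / 4))
  expect_equal(kernelMatrix(K)[1, 3], exp(-1))
  expect_equal(diag(kernelMatrix(gaussianKernel(X, h = 17))), rep(1, 3),
               ignore_attr = TRUE)

  # h -> 0+ sends every entry to 1; larger h shrinks all off-diagonals
  expect_equal(max(abs(kernelMatrix(gaussianKernel(X, 1e-12)) - 1)), 0,
               tolerance = 1e-9)
  K1 <- kernelMatrix(gaussianKernel(X, 0.5))
  K2 <- kernelMatrix(gaussianKernel(X, 2))
  off <- upper.tri(K1)
  expect_true(all(K2[off] < K1[off]))

  # degenerate input (all rows equal) errors
  expect_error(gaussianKernel(matrix(1, 4, 3)), "q = 0")
})

test_that("GB constructions commute with genotype permutations", {
  D <- polymorphicDosage(7, 15, seed = 41)
  set.seed(42)
  perm <- sample(7)
  Dp <- tetraDosage(dosageMatrix(D)[perm, ])
  for (cd in c("A", "B", "C")) {
    K <- kernelMatrix(makeKernel(D, cd, "GB"))
    Kp <- kernelMatrix(makeKernel(Dp, cd, "GB"))
    expect_equal(unname(Kp), unname(K[perm, perm]), tolerance = 1e-12)
  }
})

test_that("kernels are symmetric and PSD after clipping at model assembly", {
  D <- polymorphicDosage(8, 25, seed = 51)
  for (cd in c("B", "C")) {
    K <- kernelMatrix(makeKernel(D, cd, "GB"))
    expect_lt(max(abs(K - t(K))), 1e-10)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * max(ev))
  }
  K <- kernelMatrix(makeKernel(D, "B", "GK"))
  expect_true(all(K > 0 & K <= 1))
})

test_that("coding-A cross-product matches an independent VanRaden-style build", {
  # standardized A codes: XX'/M equals the independently standardized
  # cross-product, the conventional additive relationship construction
  D <- polymorphicDosage(6, 20, seed = 61)
  A <- codedValues(codePseudoDiploid(D))
  A <- A[, apply(A, 2, sd) > 0, drop = FALSE]  # drop constant A-codes
  mu <- colMeans(A)
  s <- sqrt(colMeans(sweep(A, 2, mu)^2))
  Z <- sweep(sweep(A, 2, mu), 2, s, "/")
  expect_lt(max(abs(tcrossprod(Z) / ncol(Z) - oracleGBAdditive(Z))), 1e-12)
})

test_that("bandwidth selection maximizes the marginal likelihood sensibly", {
  # a single-point grid returns that point
  D <- polymorphicDosage(20, 30, seed = 71)
  X <- codeAdditiveTetrasomic(D)
  set.seed(72)
  y <- rnorm(20)
  expect_equal(as.numeric(estimateBandwidth(X, y, grid = 2.5)), 2.5)

  # rescaling the marker matrix leaves the choice unchanged (q-normalized)
  g <- c(0.1, 1, 5)
  h1 <- as.numeric(estimateBandwidth(codedValues(X), y, grid = g))
  h2 <- as.numeric(estimateBandwidth(codedValues(X) * 3.7, y, grid = g))
  expect_equal(h1, h2)

  # data simulated under GK(h = 5) picks 5 over 0.1 most of the time
  wins <- 0L
  for (r in 1:20) {
    Dr <- polymorphicDosage(40, 30, seed = 500 + r)
    Xr <- codedValues(codeAdditiveTetrasomic(Dr))
    K5 <- kernelMatrix(gaussianKernel(Xr, h = 5))
    L <- chol(K5 + 1e-8 * diag(40))
    set.seed(600 + r)
    yr <- drop(t(L) %*% rnorm(40)) + rnorm(40, sd = 0.3)
    hr <- as.numeric(estimateBandwidth(Xr, yr, grid = c(0.1, 5)))
    if (abs(hr - 5) < abs(hr - 0.1)) wins <- wins + 1L
  }
  expect_gte(wins, 16L)
})
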