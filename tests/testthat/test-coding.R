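test_that("the three codings reproduce the canonical dosage-class table", {
  fx <- workedFixture()
  D <- fx$dosage

  A <- codePseudoDiploid(D)
  expect_identical(unname(codedValues(A)[, 1]), c(0, 1, 1, 1, 2))
  expect_identical(codingOf(A), "A")

  B <- codeAdditiveTetrasomic(D, standardize = FALSE)
  expect_identical(unname(codedValues(B)[, 1]), as.numeric(0:4))

  C <- codeFullTetraploid(D)
  expect_equal(unname(codedValues(C)), diag(5))
})

test_that("pseudo-diploid coding follows the 5-case lookup for all dosages", {
  lookup <- c(`0` = 0, `1` = 1, `2` = 1, `3` = 1, `4` = 2)
  set.seed(11)
  X <- matrix(sample(0:4, 60, replace = TRUE), 10, 6)
  A <- codedValues(codePseudoDiploid(tetraDosage(X)))
  expect_equal(unname(A), matrix(lookup[as.character(X)], 10, 6))
})

test_that("allele frequencies match the class-count estimator and the mean-dosage form", {
  # one marker, genotypes BBBB, ABBB, AABB, AAAB: p = (4+3+2+1)/16
  D <- tetraDosage(matrix(c(4L, 3L, 2L, 1L), 4, 1))
  fr <- alleleFreqs(D)
  expect_equal(alleleP(fr), 10 / 16)
  expect_equal(unname(classCounts(fr)[1, ]), c(0L, 1L, 1L, 1L, 1L))

  # extremes
  expect_equal(alleleP(alleleFreqs(tetraDosage(matrix(0L, 3, 2)))), c(0, 0))
  expect_equal(alleleP(alleleFreqs(tetraDosage(matrix(4L, 3, 2)))), c(1, 1))

  # property: p equals column mean dosage / 4, and rows of classCounts sum to N
  set.seed(2)
  X <- matrix(sample(0:4, 200, replace = TRUE), 20, 10)
  fr <- alleleFreqs(tetraDosage(X))
  expect_equal(alleleP(fr), unname(colMeans(X) / 4))
  expect_true(all(rowSums(classCounts(fr)) == 20))
})

test_that("standardized coding B has zero mean, unit population variance, and is idempotent", {
  # column of dosages {0, 4} in equal counts standardizes to {-1, +1}
  D <- tetraDosage(matrix(c(0L, 4L, 0L, 4L, 1L, 2L, 3L, 0L), 4, 2))
  XB <- codedValues(codeAdditiveTetrasomic(D, standardize = TRUE))
  expect_equal(unname(XB[, 1]), c(-1, 1, -1, 1))
  expect_equal(colMeans(XB), c(0, 0), ignore_attr = TRUE)
  expect_equal(colMeans(XB^2), c(1, 1), ignore_attr = TRUE)

  # standardizing the already-standardized values changes nothing
  mu <- colMeans(XB); s <- sqrt(colMeans(sweep(XB, 2, mu)^2))
  expect_equal(sweep(sweep(XB, 2, mu), 2, s, "/"), XB)

  # monomorphic column is an explicit error naming the marker
  Dm <- tetraDosage(matrix(c(2L, 2L, 2L, 0L, 1L, 3L), 3, 2,
                           dimnames = list(NULL, c("mono", "poly"))))
  expect_error(codeAdditiveTetrasomic(Dm, standardize = TRUE), "mono")
})

test_that("full-tetraploid coding is one-hot with class-count column sums", {
  set.seed(3)
  X <- matrix(sample(0:4, 18, replace = TRUE), 6, 3)
  D <- tetraDosage(X)
  C <- codedValues(codeFullTetraploid(D))
  expect_equal(dim(C), c(6L, 15L))
  # each 5-column marker block of each row sums to exactly 1
  for (j in 1:3)
    expect_equal(unname(rowSums(C[, (j - 1) * 5 + 1:5])), rep(1, 6))
  # block column sums reproduce the genotype-class tallies
  cc <- classCounts(alleleFreqs(D))
  for (j in 1:3)
    expect_equal(unname(colSums(C[, (j - 1) * 5 + 1:5])),
                 unname(cc[j, ]))
})

test_that("coding operations are deterministic and permutation-equivariant", {
  set.seed(4)
  X <- matrix(sample(0:4, 40, replace = TRUE), 8, 5,
              dimnames = list(paste0("g", 1:8), paste0("m", 1:5)))
  D <- tetraDosage(X)
  perm <- sample(8)
  Dp <- tetraDosage(X[perm, ])
  for (f in list(codePseudoDiploid, codeFullTetraploid,
                 function(d) codeAdditiveTetrasomic(d, FALSE))) {
    expect_equal(codedValues(f(Dp)), codedValues(f(D))[perm, ])
  }
})

test_that("MAF filtering keeps exactly the markers above threshold", {
  # 5 markers engineered to p = 0, small, 0.2, 0.5, 1 over 100 genotypes
  n <- 100L
  X <- cbind(rep(0L, n),                       # p = 0
             c(rep(1L, 2), rep(0L, n - 2)),    # p = 0.005
             c(rep(4L, 20), rep(0L, n - 20)),  # p = 0.2
             c(rep(4L, 50), rep(0L, n - 50)),  # p = 0.5
             rep(4L, n))                       # p = 1
  D <- tetraDosage(X)
  kept <- suppressMessages(filterMarkers(D, minMAF = 0.01))
  expect_equal(ncol(dosageMatrix(kept)), 2L)
  expect_equal(markerIds(kept), markerIds(D)[3:4])

  # no marker below threshold: identity
  Dp <- polymorphicDosage(10, 5, seed = 9)
  expect_equal(dosageMatrix(filterMarkers(Dp, 0.01, quiet = TRUE)),
               dosageMatrix(Dp))
  # removing everything is an error
  expect_error(filterMarkers(tetraDosage(matrix(0L, 4, 2)), 0.01),
               "all .* markers")
})

test_that("imputation fills round(4p) and drops high-missingness genotypes", {
  # g1 misses 2/3 markers (dropped at the 0.5 ceiling); g2 misses marker 3,
  # whose remaining observed dosages are 1 and 3 -> imputed round(4p) = 2
  X <- rbind(c(NA, 0L, NA), c(3L, 0L, NA), c(3L, 4L, 1L), c(3L, 0L, 3L))
  D <- tetraDosage(X)
  out <- suppressMessages(imputeDosages(D, maxMissing = 0.5))
  M <- dosageMatrix(out)
  expect_false(anyNA(M))
  expect_equal(nrow(M), 3L)               # g1 (2/3 missing) dropped
  expect_equal(M[1, 3], 2L)               # round(mean(c(1, 3))) = 2
  # complete input is untouched
  Dc <- polymorphicDosage(6, 4, seed = 5)
  expect_identical(dosageMatrix(imputeDosages(Dc, quiet = TRUE)),
                   dosageMatrix(Dc))
})
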