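# small complete multi-environment dataset used across model tests
simSmall <- function(n = 30, m = 80, envs = 3, seedD = 1, seedP = 2,
                     varAdd = 0.4, varNonAdd = 0, varEnv = 0.1,
                     varGxE = 0.2, varErr = 1 - varAdd - varNonAdd -
                       varEnv - varGxE, rho = 0) {
  cfg <- simConfig(nGenotypes = n, nMarkers = m, nEnvironments = envs,
                   varAdd = varAdd, varNonAdd = varNonAdd, varEnv = varEnv,
                   varGxE = varGxE, varErr = varErr,
                   envGeneticCorrelation = rho, subsetEnv = NA)
  D <- simulateDosages(cfg, seed = seedD)
  sim <- simulatePhenotypes(D, cfg, seed = seedP)
  list(D = suppressMessages(filterMarkers(D, 0.01, quiet = TRUE)),
       pheno = sim$pheno, truth = sim$truth)
}

test_that("buildModel assembles the advertised covariance structures", {
  s <- simSmall()
  KB <- makeKernel(s$D, "B", "GB")
  KC <- makeKernel(s$D, "C", "GB")

  # model 1 needs a single environment
  ph1 <- s$pheno[s$pheno$environment_id == "env1", ]
  m1 <- buildModel(ph1, "sim_trait", KB, 1)
  expect_equal(vapply(m1@components, `[[`, "", "label"), "g")
  expect_error(buildModel(s$pheno, "sim_trait", KB, 1), "single-environment")

  # model 3: env + g + gxe; model 4: env + g1 + g1xe + g2 + g2xe
  m3 <- buildModel(s$pheno, "sim_trait", KB, 3)
  expect_equal(vapply(m3@components, `[[`, "", "label"),
               c("env", "g", "gxe"))
  m4 <- buildModel(s$pheno, "sim_trait", list(KB, KC), 4)
  expect_equal(vapply(m4@components, `[[`, "", "label"),
               c("env", "g1", "g1xe", "g2", "g2xe"))

  # missing genotypes in the kernel are named
  bad <- s$pheno
  bad$genotype_id[1] <- "ghost"
  expect_error(buildModel(bad, "sim_trait", KB, 3), "ghost")
})

test_that("with K = identity the genetic covariance of model 1 is sigma2 * I", {
  # three observations, identity kernel: the g component's eigenbasis must
  # span I with unit eigenvalues
  ph <- data.frame(genotype_id = c("a", "b", "c"), environment_id = "e1",
                   trait = "t", value = c(1, 2, 3))
  I3 <- diag(3)
  dimnames(I3) <- list(c("a", "b", "c"), c("a", "b", "c"))
  K <- new("GenomicKernel", kernel = I3, method = "GB", coding = "B",
           bandwidth = NA_real_, qMedian = NA_real_)
  m <- buildModel(ph, "t", K, 1)
  cmp <- m@components[[1]]
  expect_equal(sort(cmp$d), rep(1, 3))
  expect_equal(cmp$U %*% diag(cmp$d) %*% t(cmp$U), diag(3))
})

test_that("Hadamard interaction covariance equals the Kronecker form on balanced data", {
  # 4 genotypes x 2 environments, E = I, cells ordered env-major
  set.seed(5)
  A <- matrix(rnorm(16), 4)
  K <- crossprod(A) / 4
  gids <- paste0("g", 1:4)
  dimnames(K) <- list(gids, gids)
  ph <- data.frame(genotype_id = rep(gids, 2),
                   environment_id = rep(c("e1", "e2"), each = 4),
                   trait = "t", value = rnorm(8))
  kern <- new("GenomicKernel", kernel = K, method = "GB", coding = "B",
              bandwidth = NA_real_, qMedian = NA_real_)
  m <- buildModel(ph, "t", kern, 3)
  gxe <- m@components[[3]]
  Sigma <- gxe$U %*% diag(gxe$d) %*% t(gxe$U)
  expect_equal(unname(Sigma), kronecker(diag(2), unname(K)),
               tolerance = 1e-9)
})

test_that("Gibbs posterior mean matches closed-form BLUP with fixed variances", {
  s <- simSmall(n = 20, m = 60, envs = 1, varAdd = 0.5, varEnv = 0,
                varGxE = 0, seedD = 31, seedP = 32)
  K <- makeKernel(s$D, "B", "GB")
  m <- buildModel(s$pheno, "sim_trait", K, 1)
  fit <- fitGibbs(m, nIter = 5000, burnIn = 1000, thin = 2, seed = 33,
                  fixVariances = c(g = 0.5, residual = 0.5),
                  traceEffects = TRUE)
  oracle <- oracleBLUP(s$pheno$value, kernelMatrix(K), 0.5, 0.5)
  tr <- fit@effectTraces$g
  ess <- apply(tr, 1, function(x) max(1, tetraGP:::.ess(x)))
  mcse <- apply(tr, 1, sd) / sqrt(ess)
  expect_true(all(abs(fit@effects$g - oracle$g) <= 3 * mcse))
})

test_that("strong shrinkage collapses predictions toward the overall mean", {
  s <- simSmall(n = 20, m = 50, envs = 1, varAdd = 0.4, varEnv = 0,
                varGxE = 0, seedD = 41, seedP = 42)
  K <- makeKernel(s$D, "B", "GB")
  ph <- s$pheno
  ph$value[1:5] <- NA
  m <- buildModel(ph, "sim_trait", K, 1)
  fit <- fitGibbs(m, nIter = 2000, burnIn = 500, thin = 2, seed = 43,
                  fixVariances = c(g = 1e-8, residual = 10))
  pr <- predictions(fit)
  expect_lt(max(abs(pr$predicted - mean(ph$value, na.rm = TRUE))), 0.15)
})

test_that("a test genotype duplicating a training genotype inherits its genetic value", {
  s <- simSmall(n = 15, m = 40, envs = 1, varAdd = 0.6, varEnv = 0,
                varGxE = 0, varErr = 0.4, seedD = 51, seedP = 52)
  X <- dosageMatrix(s$D)
  X <- rbind(X, dup = X[1, ])  # genotype "dup" identical to genotype 1
  D2 <- tetraDosage(X)
  K <- makeKernel(D2, "B", "GB")
  ph <- s$pheno
  ph <- rbind(ph, data.frame(genotype_id = "dup", environment_id = "env1",
                             trait = "sim_trait", value = NA))
  m <- buildModel(ph, "sim_trait", K, 1)
  fit <- fitGibbs(m, nIter = 4000, burnIn = 1000, thin = 2, seed = 53)
  pred <- predictions(fit)$predicted
  fittedG1 <- fit@fitted[1]
  expect_lt(abs(pred - fittedG1), 0.05 * max(1, abs(fittedG1)))
})

test_that("fixing the seed reproduces posterior summaries bit-for-bit", {
  s <- simSmall(n = 20, m = 40)
  K <- makeKernel(s$D, "B", "GB")
  ph <- s$pheno
  ph$value[c(3, 17, 40)] <- NA
  run <- function() fitGibbs(buildModel(ph, "sim_trait", K, 3),
                             nIter = 1200, burnIn = 400, thin = 2,
                             seed = 99)
  f1 <- run(); f2 <- run()
  expect_identical(f1@varTrace, f2@varTrace)
  expect_identical(f1@fitted, f2@fitted)

  # prediction length matches the request; unknown cells are an error
  pr <- predict(f1, ph[c(3, 17), c("genotype_id", "environment_id")])
  expect_equal(nrow(pr), 2L)
  expect_error(predict(f1, data.frame(genotype_id = "nobody",
                                      environment_id = "env1")),
               "nobody")
})

test_that("model 2 with the second kernel silenced reproduces model 1", {
  s <- simSmall(n = 25, m = 60, envs = 1, varAdd = 0.5, varEnv = 0,
                varGxE = 0, seedD = 61, seedP = 62)
  KB <- makeKernel(s$D, "B", "GB")
  KC <- makeKernel(s$D, "C", "GB")
  ph <- s$pheno
  ph$value[1:6] <- NA
  m1 <- buildModel(ph, "sim_trait", KB, 1)
  f1 <- fitGibbs(m1, nIter = 4000, burnIn = 1000, thin = 2, seed = 63,
                 fixVariances = c(g = 0.4, residual = 0.5))
  m2 <- buildModel(ph, "sim_trait", list(KB, KC), 2)
  f2 <- fitGibbs(m2, nIter = 4000, burnIn = 1000, thin = 2, seed = 63,
                 fixVariances = c(g1 = 0.4, g2 = 1e-9, residual = 0.5))
  expect_lt(max(abs(predictions(f1)$predicted -
                      predictions(f2)$predicted)), 0.1)
})

test_that("posterior variance components roughly reconstruct var(y) when well-specified", {
  s <- simSmall(n = 60, m = 150, envs = 3, varAdd = 0.35, varEnv = 0.1,
                varGxE = 0.2, seedD = 71, seedP = 72)
  K <- makeKernel(s$D, "B", "GB")
  m <- buildModel(s$pheno, "sim_trait", K, 3)
  fit <- fitGibbs(m, nIter = 3000, burnIn = 1000, thin = 2, seed = 73)
  v <- varianceComponents(fit)
  diags <- vapply(m@components, `[[`, 0, "meanDiag")
  total <- sum(v$mean[seq_along(diags)] * diags) +
    v$mean[v$component == "residual"]
  expect_lt(abs(total - var(s$pheno$value)) / var(s$pheno$value), 0.25)
})

test_that("degenerate MCMC configurations are rejected", {
  s <- simSmall(n = 12, m = 30, envs = 1, varAdd = 0.5, varEnv = 0,
                varGxE = 0)
  K <- makeKernel(s$D, "B", "GB")
  m <- buildModel(s$pheno, "sim_trait", K, 1)
  expect_error(fitGibbs(m, nIter = 100, burnIn = 200), "burnIn")
  expect_error(fitGibbs(m, nIter = 300, burnIn = 200, thin = 2),
               "retained")
  expect_error(fitGibbs(m, fixVariances = c(bogus = 1)), "bogus")
})
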