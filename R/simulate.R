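#' Configuration for the synthetic tetraploid study generator
#'
#' Validated parameter set for \code{\link{simulateDosages}} and
#' \code{\link{simulatePhenotypes}}.  The defaults emulate the scale and
#' structure of a Nordic multi-site potato trial: ~250 tetraploid
#' genotypes scored at ~2,000 biallelic SNPs under tetrasomic
#' Hardy-Weinberg sampling, three sites with positively correlated
#' genetic effects, and one site holding only about two thirds of the
#' lines.  Variance fractions partition a unit-variance trait into
#' additive, non-additive (genotype-class), environment main-effect,
#' genotype-by-environment and residual components.
#'
#' @param nGenotypes,nMarkers,nEnvironments problem dimensions
#'   (defaults 250, 2000, 3).
#' @param alleleFreqRange range the per-marker B-allele frequency is drawn
#'   uniformly from (default c(0.05, 0.95)).
#' @param varAdd,varNonAdd,varEnv,varGxE,varErr variance fractions; must
#'   be non-negative and sum to 1 (defaults 0.3, 0.1, 0.1, 0.2, 0.3).
#' @param envGeneticCorrelation compound-symmetry correlation of the G x E
#'   deviations across environments, in [-1, 1] (default 0; positive
#'   inter-site genetic correlation already arises from the shared
#'   additive effects).
#' @param subsetEnv index of the environment observed on only a subset of
#'   genotypes (default 1; \code{NA} for complete data).
#' @param subsetFrac fraction of genotypes observed in that environment
#'   (default 169/256, the incomplete-site ratio the generator emulates).
#' @return a list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nGenotypes = 250L, nMarkers = 2000L,
                      nEnvironments = 3L,
                      alleleFreqRange = c(0.05, 0.95),
                      varAdd = 0.3, varNonAdd = 0.1, varEnv = 0.1,
                      varGxE = 0.2, varErr = 0.3,
                      envGeneticCorrelation = 0,
                      subsetEnv = 1L, subsetFrac = 169 / 256) {
  fr <- c(varAdd, varNonAdd, varEnv, varGxE, varErr)
  if (any(fr < 0)) stop("variance fractions must be non-negative")
  if (abs(sum(fr) - 1) > 1e-9) stop("variance fractions must sum to 1")
  if (nGenotypes < 10L) stop("need at least 10 genotypes")
  if (envGeneticCorrelation < -1 || envGeneticCorrelation > 1)
    stop("envGeneticCorrelation must lie in [-1, 1]")
  stopifnot(length(alleleFreqRange) == 2L,
            all(alleleFreqRange >= 0), all(alleleFreqRange <= 1))
  structure(list(nGenotypes = as.integer(nGenotypes),
                 nMarkers = as.integer(nMarkers),
                 nEnvironments = as.integer(nEnvironments),
                 alleleFreqRange = alleleFreqRange,
                 varAdd = varAdd, varNonAdd = varNonAdd, varEnv = varEnv,
                 varGxE = varGxE, varErr = varErr,
                 envGeneticCorrelation = envGeneticCorrelation,
                 subsetEnv = subsetEnv, subsetFrac = subsetFrac),
            class = "SimConfig")
}

#' Simulate tetraploid SNP dosages
#'
#' Per marker, a B-allele frequency p is drawn uniformly from the
#' configured range; each genotype's dosage is then Binomial(4, p) --
#' tetrasomic Hardy-Weinberg sampling (double reduction ignored).
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param seed integer seed.
#' @return a \code{\linkS4class{TetraDosage}}.
#' @export
simulateDosages <- function(cfg = simConfig(), seed = 1L) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(as.integer(seed))
  p <- runif(cfg$nMarkers, cfg$alleleFreqRange[1L], cfg$alleleFreqRange[2L])
  X <- vapply(p, function(pi) rbinom(cfg$nGenotypes, 4L, pi),
              integer(cfg$nGenotypes))
  tetraDosage(X)
}

## scale a vector/matrix of effects to an exact target (population)
## variance; returns zeros when the target is 0 or the draw is constant
.scaleToVar <- function(x, target) {
  if (target <= 0) return(x * 0)
  v <- mean((x - mean(x))^2)
  if (v == 0) return(x * 0)
  (x - mean(x)) * sqrt(target / v)
}

#' Simulate multi-environment phenotypes over a dosage matrix
#'
#' Generates one trait with the covariance structure the multi-environment
#' kernel regression models assume: additive values from the standardized
#' additive-tetrasomic (B) coding times iid marker effects; non-additive
#' values from the one-hot full-tetraploid (C) coding times iid
#' genotype-class effects; random environment main effects; G x E
#' deviations with genetic covariance proportional to the additive kernel
#' and a compound-symmetry correlation across environments; iid residuals.
#' Each component is rescaled to its exact target variance fraction, so a
#' unit-variance trait decomposes as configured.  One environment may be
#' observed on only a subset of lines, mirroring incomplete
#' multi-site trials.
#'
#' @param D a complete \code{\linkS4class{TetraDosage}}.
#' @param cfg a \code{\link{simConfig}}.
#' @param seed integer seed.
#' @param trait trait name used in the phenotype table (default
#'   \code{"sim_trait"}).
#' @return list with \code{pheno} (long-format phenotype data.frame:
#'   genotype_id, environment_id, trait, value) and \code{truth} (list of
#'   the generated additive, non-additive, environment and G x E effects
#'   and the realized variance fractions).
#' @export
simulatePhenotypes <- function(D, cfg = simConfig(), seed = 1L,
                               trait = "sim_trait") {
  stopifnot(is(D, "TetraDosage"), inherits(cfg, "SimConfig"))
  set.seed(as.integer(seed) + 7L)
  n <- nrow(dosageMatrix(D))
  s <- cfg$nEnvironments
  gids <- genotypeIds(D)
  envs <- paste0("env", seq_len(s))

  Dp <- filterMarkers(D, minMAF = 0.001, quiet = TRUE)

  # additive component
  add <- rep(0, n)
  if (cfg$varAdd > 0) {
    XB <- codedValues(codeAdditiveTetrasomic(Dp, standardize = TRUE))
    add <- .scaleToVar(drop(XB %*% rnorm(ncol(XB))), cfg$varAdd)
  }

  # non-additive genotype-class component
  nonadd <- rep(0, n)
  if (cfg$varNonAdd > 0) {
    XC <- codedValues(codeFullTetraploid(Dp))
    nonadd <- .scaleToVar(drop(XC %*% rnorm(ncol(XC))), cfg$varNonAdd)
  }

  # environment main effects
  env <- rep(0, s)
  if (cfg$varEnv > 0)
    env <- .scaleToVar(rnorm(s), cfg$varEnv)

  # G x E deviations: genetic covariance ~ additive kernel, compound
  # symmetry across environments
  ge <- matrix(0, n, s)
  if (cfg$varGxE > 0) {
    XB <- codedValues(codeAdditiveTetrasomic(Dp, standardize = TRUE))
    W <- XB %*% matrix(rnorm(ncol(XB) * s), ncol(XB), s) / sqrt(ncol(XB))
    rho <- cfg$envGeneticCorrelation
    R <- matrix(rho, s, s); diag(R) <- 1
    ge <- W %*% chol(R)
    ge <- (ge - mean(ge)) * sqrt(cfg$varGxE / mean((ge - mean(ge))^2))
  }

  eps <- matrix(0, n, s)
  if (cfg$varErr > 0)
    eps <- matrix(.scaleToVar(rnorm(n * s), cfg$varErr), n, s)

  Y <- outer(add + nonadd, rep(1, s)) +
       outer(rep(1, n), env) + ge + eps
  pheno <- data.frame(
    genotype_id = rep(gids, times = s),
    environment_id = rep(envs, each = n),
    trait = trait,
    value = as.numeric(Y),
    stringsAsFactors = FALSE)

  if (!is.na(cfg$subsetEnv) && cfg$subsetEnv >= 1 &&
      cfg$subsetEnv <= s && cfg$subsetFrac < 1) {
    keepN <- max(2L, round(cfg$subsetFrac * n))
    kept <- sort(sample(gids, keepN))
    drop <- pheno$environment_id == envs[cfg$subsetEnv] &
      !(pheno$genotype_id %in% kept)
    pheno <- pheno[!drop, , drop = FALSE]
  }
  rownames(pheno) <- NULL

  truth <- list(additive = stats::setNames(add, gids),
                nonAdditive = stats::setNames(nonadd, gids),
                envEffects = stats::setNames(env, envs),
                gxe = `dimnames<-`(ge, list(gids, envs)),
                realized = c(varAdd = mean((add - mean(add))^2),
                             varNonAdd = mean((nonadd - mean(nonadd))^2),
                             varGxE = mean((ge - mean(ge))^2),
                             varErr = mean((eps - mean(eps))^2)))
  list(pheno = pheno, truth = truth)
}

#' Worked one-marker coding fixture
#'
#' Five genotypes spanning the dosage classes 0..4 (AAAA, AAAB, AABB,
#' ABBB, BBBB) at a single marker, with the golden expected codings and
#' brute-force relationship matrices computed independently of the
#' package's kernel functions (plain double loops over the printed
#' formulas).
#'
#' @return list with \code{dosage} (a \code{TetraDosage}),
#'   \code{codingA}, \code{codingB}, \code{codingC} (expected coded
#'   values), \code{p} (the tetraploid allele frequency, 0.5), and
#'   \code{gbA}, \code{gbC} (brute-force GB matrices for codings A and C).
#' @export
workedFixture <- function() {
  dos <- matrix(0:4, 5, 1,
                dimnames = list(paste0("geno", 0:4), "SNP1"))
  D <- tetraDosage(dos)
  codingA <- matrix(c(0, 1, 1, 1, 2), 5, 1,
                    dimnames = dimnames(dos))
  codingB <- matrix(as.numeric(0:4), 5, 1, dimnames = dimnames(dos))
  codingC <- diag(5)
  dimnames(codingC) <- list(rownames(dos),
                            paste("SNP1", c("AAAA", "AAAB", "AABB",
                                            "ABBB", "BBBB"), sep = "."))
  p <- mean(dos) / 4  # 0.5

  # brute-force pseudo-diploid GB (double loop over the printed formulas)
  xA <- codingA[, 1L]
  gbA <- matrix(0, 5, 5, dimnames = list(rownames(dos), rownames(dos)))
  for (j in 1:5) for (k in 1:5) {
    gbA[j, k] <- if (j == k)
      1 + (xA[j]^2 - (1 + 2 * p) * xA[j] + 2 * p^2) / (2 * p * (1 - p))
    else
      (xA[j] - 2 * p) * (xA[k] - 2 * p) / (2 * p * (1 - p))
  }

  # brute-force full-tetraploid GB: class frequencies all 1/5, M = 5
  pc <- rep(1 / 5, 5)
  gbC <- matrix(0, 5, 5, dimnames = list(rownames(dos), rownames(dos)))
  for (j in 1:5) for (k in 1:5) {
    if (j == k) {
      acc <- 0
      for (i in 1:5)
        acc <- acc + (codingC[j, i]^2 - 2 * pc[i] * codingC[j, i] +
                        pc[i]^2) / (pc[i] * (1 - pc[i]))
      gbC[j, k] <- 1 + acc / 5
    } else {
      acc <- 0
      for (i in 1:5)
        acc <- acc + (codingC[j, i] - pc[i]) * (codingC[k, i] - pc[i]) /
          (pc[i] * (1 - pc[i]))
      gbC[j, k] <- acc / 5
    }
  }

  list(dosage = D, codingA = codingA, codingB = codingB,
       codingC = codingC, p = p, gbA = gbA, gbC = gbC)
}
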