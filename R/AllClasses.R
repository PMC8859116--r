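#' @import methods
#' @importFrom stats cor dist dnorm median optimize qnorm rbinom
#'   rchisq rnorm runif sd var
NULL

#' Tetraploid allele-dosage matrix
#'
#' Container for a genotype-by-marker matrix of tetraploid allele dosages:
#' each entry counts copies of the alternative (B) allele in {0, 1, 2, 3, 4},
#' corresponding to the genotype classes AAAA, AAAB, AABB, ABBB and BBBB of
#' a polysomic tetraploid.  Missing calls are allowed (\code{NA}) until
#' resolved with \code{\link{imputeDosages}}; downstream coding and kernel
#' operations require a complete matrix.
#'
#' @slot dosage integer matrix, genotypes in rows, markers in columns,
#'   with unique row (genotype) and column (marker) names.
#'
#' @seealso \code{\link{tetraDosage}}, \code{\link{codePseudoDiploid}},
#'   \code{\link{codeAdditiveTetrasomic}}, \code{\link{codeFullTetraploid}}
#' @export
setClass("TetraDosage", representation(dosage = "matrix"))

setValidity("TetraDosage", function(object) {
  d <- object@dosage
  if (!is.numeric(d)) return("dosage must be a numeric/integer matrix")
  if (nrow(d) < 2L) return("need at least 2 genotypes")
  if (ncol(d) < 1L) return("need at least 1 marker")
  if (is.null(rownames(d)) || is.null(colnames(d)))
    return("dosage matrix must carry genotype rownames and marker colnames")
  if (anyDuplicated(rownames(d))) return("duplicated genotype ids")
  if (anyDuplicated(colnames(d))) return("duplicated marker ids")
  v <- d[!is.na(d)]
  if (any(v != round(v)) || any(v < 0) || any(v > 4))
    return("dosages must be integers in 0..4 (count of B alleles)")
  TRUE
})

#' Coded marker matrix
#'
#' A dosage matrix recoded under one of the three marker codings:
#' \describe{
#'   \item{A (pseudo-diploid)}{0 for AAAA, 2 for BBBB, 1 for any
#'     heterozygote; N x M.}
#'   \item{B (additive tetrasomic)}{the raw dosage 0..4, optionally
#'     standardized by column to mean 0 and unit (population) variance;
#'     N x M.}
#'   \item{C (full tetraploid)}{one-hot indicator of the genotype class,
#'     five columns per marker in the fixed order AAAA, AAAB, AABB, ABBB,
#'     BBBB; N x 5M.}
#' }
#'
#' @slot values numeric matrix of coded values.
#' @slot coding one of \code{"A"}, \code{"B"}, \code{"C"}.
#' @slot standardized logical; \code{TRUE} only for column-standardized
#'   coding B.
#' @slot columnFreqs per-column frequency: allele frequency p for codings
#'   A/B, observed genotype-class frequency for coding C.
#' @export
setClass("CodedMarkers",
  representation(values = "matrix", coding = "character",
                 standardized = "logical", columnFreqs = "numeric"))

setValidity("CodedMarkers", function(object) {
  if (!object@coding %in% c("A", "B", "C")) return("coding must be A, B or C")
  if (length(object@standardized) != 1L) return("standardized must be scalar")
  if (length(object@columnFreqs) != ncol(object@values))
    return("columnFreqs length must match number of columns")
  if (object@coding != "B" && object@standardized)
    return("only coding B supports standardization")
  TRUE
})

#' Tetraploid allele and genotype-class frequencies
#'
#' Per-marker frequency of the B allele,
#' p = (4 n_bbbb + 3 n_abbb + 2 n_aabb + n_aaab) / (4N),
#' together with the genotype-class counts it is derived from.
#'
#' @slot p length-M numeric vector of B-allele frequencies in [0, 1].
#' @slot classCounts M x 5 integer matrix of genotype-class counts
#'   (columns AAAA, AAAB, AABB, ABBB, BBBB); each row sums to N.
#' @export
setClass("AlleleFreqs",
  representation(p = "numeric", classCounts = "matrix"))

setValidity("AlleleFreqs", function(object) {
  if (ncol(object@classCounts) != 5L) return("classCounts needs 5 columns")
  if (nrow(object@classCounts) != length(object@p))
    return("p and classCounts disagree on marker count")
  if (any(object@p < 0 | object@p > 1)) return("p must lie in [0, 1]")
  n <- rowSums(object@classCounts)
  if (length(unique(n)) > 1L) return("class counts must sum to N per marker")
  TRUE
})

#' Genomic similarity kernel
#'
#' An N x N symmetric positive semi-definite genetic similarity matrix,
#' either the linear GBLUP relationship matrix (\code{method = "GB"}) or the
#' Gaussian kernel \code{exp(-h d^2 / q)} (\code{method = "GK"}), with the
#' provenance needed to reproduce it.
#'
#' @slot kernel symmetric numeric matrix with genotype ids as dimnames.
#' @slot method \code{"GB"} or \code{"GK"}.
#' @slot coding marker coding the kernel was built from (\code{"A"},
#'   \code{"B"} or \code{"C"}).
#' @slot bandwidth Gaussian bandwidth h (\code{NA} for GB).
#' @slot qMedian median off-diagonal squared Euclidean distance used to
#'   normalize the Gaussian kernel (\code{NA} for GB).
#' @export
setClass("GenomicKernel",
  representation(kernel = "matrix", method = "character",
                 coding = "character", bandwidth = "numeric",
                 qMedian = "numeric"))

setValidity("GenomicKernel", function(object) {
  K <- object@kernel
  if (nrow(K) != ncol(K)) return("kernel must be square")
  if (is.null(rownames(K))) return("kernel must carry genotype ids")
  if (max(abs(K - t(K))) > 1e-10) return("kernel must be symmetric")
  if (!object@method %in% c("GB", "GK")) return("method must be GB or GK")
  if (!object@coding %in% c("A", "B", "C")) return("coding must be A, B or C")
  TRUE
})

#' Assembled Bayesian G x E regression model
#'
#' The observation-level structure of one of the four kernel regression
#' models, ready for Gibbs sampling: phenotype vector (with NA marking
#' cells to predict), cell identities, and one eigendecomposed covariance
#' structure per random component.
#'
#' @slot y numeric phenotype vector over all cells; NA = cell to predict.
#' @slot cells data.frame with columns \code{genotype_id},
#'   \code{environment_id}, aligned with \code{y}.
#' @slot observed logical vector, TRUE where y is observed.
#' @slot components list; one entry per random component with elements
#'   \code{label}, \code{U} (n_obs x k eigenvectors), \code{d}
#'   (k eigenvalues), \code{P} (n_test x k predictor matrix),
#'   \code{meanDiag} (mean covariance diagonal over observed cells).
#' @slot modelId integer 1-4.
#' @slot trait trait name.
#' @export
setClass("GxEModel",
  representation(y = "numeric", cells = "data.frame", observed = "logical",
                 components = "list", modelId = "integer", trait = "character"))

#' Fitted Bayesian G x E regression model
#'
#' Posterior summaries from \code{\link{fitGibbs}}: intercept, variance
#' components (with retained-sample traces), posterior-mean random effects
#' per component, fitted values for observed cells and predictions for
#' masked cells.
#'
#' @slot muMean,muSd posterior mean and sd of the intercept.
#' @slot variances data.frame: component, posterior mean, sd, median.
#' @slot varTrace retained-sample trace matrix (columns: one per variance
#'   component, residual, mu).
#' @slot effects list of posterior-mean effect vectors (observed cells),
#'   one per component.
#' @slot effectTraces list of effect trace matrices (empty unless requested).
#' @slot cells,observed cell table and observation mask from the model.
#' @slot fitted posterior-mean fitted genetic value (mu + all random
#'   effects, no residual) for every cell.
#' @slot predSd posterior sd of the fitted/predicted value per cell.
#' @slot config list of MCMC settings used.
#' @slot modelId integer 1-4.
#' @slot trait trait name.
#' @export
setClass("GxEFit",
  representation(muMean = "numeric", muSd = "numeric",
                 variances = "data.frame", varTrace = "matrix",
                 effects = "list", effectTraces = "list",
                 cells = "data.frame", observed = "logical",
                 fitted = "numeric", predSd = "numeric",
                 config = "list", modelId = "integer", trait = "character"))

#' Cross-validation plan
#'
#' Train/test masks for one of the two validation schemes:
#' \code{single_env_random} (random 70/30-style genotype partitions within
#' one environment, repeated) or \code{CV2} (multi-environment fold masks
#' where a line is predicted in one site while its records at other sites
#' stay in training).
#'
#' @slot scheme \code{"single_env_random"} or \code{"CV2"}.
#' @slot masks list of replicates; each replicate is a list of folds; each
#'   fold a vector identifying the test units (genotype ids for
#'   single-environment, cell row indices for CV2).
#' @slot cells for CV2, the data.frame of candidate cells the indices
#'   refer to; empty otherwise.
#' @slot seed integer seed the plan was generated from.
#' @slot params list of scheme parameters (train_frac, n_reps, n_folds).
#' @export
setClass("CVPlan",
  representation(scheme = "character", masks = "list", cells = "data.frame",
                 seed = "integer", params = "list"))
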