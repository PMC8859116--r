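## PSD is enforced where kernels enter a model (buildModel eigendecomposes
## and drops non-positive eigenvalues): the pseudo-diploid GB uses an
## expected-value diagonal that legitimately dips below the cross-product
## diagonal for heterozygote-rich tetraploid data, so its spectrum can
## carry real negative eigenvalues that must be clipped, not rejected.
.newKernel <- function(K, method, coding, bandwidth = NA_real_,
                       qMedian = NA_real_) {
  K <- (K + t(K)) / 2  # remove floating-point asymmetry
  new("GenomicKernel", kernel = K, method = method, coding = coding,
      bandwidth = bandwidth, qMedian = qMedian)
}

#' Pseudo-diploid GBLUP relationship matrix
#'
#' Linear relationship matrix for the pseudo-diploid coding (A).  For
#' lines j, k and markers i with allele frequency p_i,
#' \deqn{GB_{jk} = \frac{1}{M}\sum_i
#'   \frac{(x_{ji}-2p_i)(x_{ki}-2p_i)}{2p_i(1-p_i)}}
#' and the diagonal
#' \deqn{GB_{jj} = 1 + \frac{1}{M}\sum_i
#'   \frac{x_{ji}^2-(1+2p_i)x_{ji}+2p_i^2}{2p_i(1-p_i)}.}
#'
#' @param XA a \code{\linkS4class{CodedMarkers}} with coding A.
#' @param freqs the matching \code{\linkS4class{AlleleFreqs}} (tetraploid
#'   allele frequencies of the underlying dosages).
#' @return a \code{\linkS4class{GenomicKernel}} (method GB, coding A).
#' @export
gbPseudoDiploid <- function(XA, freqs) {
  stopifnot(is(XA, "CodedMarkers"), is(freqs, "AlleleFreqs"))
  if (XA@coding != "A") stop("gbPseudoDiploid expects coding A")
  X <- XA@values
  p <- alleleP(freqs)
  if (length(p) != ncol(X)) stop("freqs do not match the coded matrix")
  if (any(p <= 0 | p >= 1))
    stop("allele frequency 0 or 1 at marker(s) ",
         paste(colnames(X)[p <= 0 | p >= 1], collapse = ", "),
         "; run filterMarkers() first")
  M <- ncol(X)
  w <- 1 / sqrt(2 * p * (1 - p))
  Z <- sweep(sweep(X, 2L, 2 * p, "-"), 2L, w, "*")
  K <- tcrossprod(Z) / M
  # the printed diagonal differs from the cross-product diagonal
  diag(K) <- 1 + colSums((t(X)^2 - (1 + 2 * p) * t(X) + 2 * p^2) /
                           (2 * p * (1 - p))) / M
  .newKernel(K, "GB", "A")
}

#' Additive tetrasomic GBLUP relationship matrix
#'
#' GB = XX'/M over the column-standardized additive tetrasomic coding (B).
#' Under the population-variance standardization the mean diagonal is
#' exactly 1.
#'
#' @param XB a standardized \code{\linkS4class{CodedMarkers}} with coding B.
#' @return a \code{\linkS4class{GenomicKernel}} (method GB, coding B).
#' @export
gbAdditive <- function(XB) {
  stopifnot(is(XB, "CodedMarkers"))
  if (XB@coding != "B") stop("gbAdditive expects coding B")
  if (!XB@standardized)
    stop("gbAdditive expects the standardized coding-B matrix; use ",
         "codeAdditiveTetrasomic(D, standardize = TRUE)")
  X <- XB@values
  .newKernel(tcrossprod(X) / ncol(X), "GB", "B")
}

#' Full-tetraploid GBLUP relationship matrix
#'
#' Relationship matrix over the one-hot full-tetraploid coding (C), with
#' p the observed frequency of each genotype-class column and M the number
#' of retained effect columns (markers x 5 minus dropped empty classes):
#' \deqn{GB_{jk} = \frac{1}{M}\sum_i
#'   \frac{(x_{ji}-p_i)(x_{ki}-p_i)}{p_i(1-p_i)}}
#' with diagonal
#' \deqn{GB_{jj} = 1 + \frac{1}{M}\sum_i
#'   \frac{x_{ji}^2-2p_ix_{ji}+p_i^2}{p_i(1-p_i)}.}
#' Genotype-class columns with observed frequency 0 or 1 carry no signal
#' and are dropped before the sum (with a message), adjusting M.
#'
#' @param XC a \code{\linkS4class{CodedMarkers}} with coding C.
#' @param quiet suppress the dropped-column message.
#' @return a \code{\linkS4class{GenomicKernel}} (method GB, coding C).
#' @export
gbFullTetraploid <- function(XC, quiet = FALSE) {
  stopifnot(is(XC, "CodedMarkers"))
  if (XC@coding != "C") stop("gbFullTetraploid expects coding C")
  X <- XC@values
  p <- XC@columnFreqs
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("no polymorphic genotype-class columns")
  if (!quiet && any(!keep))
    message("gbFullTetraploid: dropped ", sum(!keep),
            " genotype-class columns with frequency 0 or 1")
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  M <- ncol(X)
  w <- 1 / sqrt(p * (1 - p))
  Z <- sweep(sweep(X, 2L, p, "-"), 2L, w, "*")
  K <- tcrossprod(Z) / M
  diag(K) <- 1 + colSums((t(X)^2 - 2 * p * t(X) + p^2) / (p * (1 - p))) / M
  .newKernel(K, "GB", "C")
}

#' Squared Euclidean distance matrix between genotypes
#'
#' \eqn{d^2_{ii'} = \sum_k (x_{ik} - x_{i'k})^2} over the columns of a
#' coded marker matrix.
#'
#' @param X a \code{\linkS4class{CodedMarkers}} or numeric matrix.
#' @return symmetric N x N matrix with zero diagonal.
#' @export
squaredDistanceMatrix <- function(X) {
  if (is(X, "CodedMarkers")) X <- X@values
  X <- as.matrix(X)
  D2 <- as.matrix(dist(X, method = "euclidean"))^2
  diag(D2) <- 0
  D2
}

#' Gaussian kernel
#'
#' GK = exp(-h d^2 / q) where d^2 is the squared Euclidean distance
#' between the coded marker rows of two genotypes and q is the median of
#' the off-diagonal squared distances (so h is scale-free).
#'
#' @param X a \code{\linkS4class{CodedMarkers}} or numeric matrix.
#' @param h positive bandwidth controlling the covariance decay rate
#'   (default 1).
#' @param coding coding label recorded on the kernel (taken from \code{X}
#'   when it is a \code{CodedMarkers}).
#' @return a \code{\linkS4class{GenomicKernel}} (method GK) with unit
#'   diagonal and entries in (0, 1].
#' @examples
#' X <- matrix(c(0, 1, 0, 0, 0, 2), 3, 2)
#' kernelMatrix(gaussianKernel(X, h = 1))[1, 2]  # exp(-1/4)
#' @export
gaussianKernel <- function(X, h = 1, coding = NULL) {
  if (is(X, "CodedMarkers") && is.null(coding)) coding <- X@coding
  if (is.null(coding)) coding <- "B"
  stopifnot(h > 0)
  D2 <- squaredDistanceMatrix(X)
  q <- median(D2[upper.tri(D2)])
  if (!is.finite(q) || q <= 0)
    stop("degenerate distance matrix (all genotypes identical): q = 0")
  K <- exp(-h * D2 / q)
  diag(K) <- 1
  if (is.null(rownames(K)))
    dimnames(K) <- list(sprintf("G%03d", seq_len(nrow(K))),
                        sprintf("G%03d", seq_len(nrow(K))))
  .newKernel(K, "GK", coding, bandwidth = h, qMedian = q)
}

## profiled Gaussian-process marginal log-likelihood of
## y = mu*1 + g + e, g ~ N(0, s2g K), e ~ N(0, s2e I)
.kernelMarginalLogLik <- function(K, y) {
  eg <- eigen(K, symmetric = TRUE)
  U <- eg$vectors
  d <- pmax(eg$values, 0)
  yt <- drop(crossprod(U, y))
  ot <- drop(crossprod(U, rep(1, length(y))))
  n <- length(y)
  nll <- function(loglambda) {   # lambda = s2g / s2e
    lambda <- exp(loglambda)
    v <- lambda * d + 1
    mu <- sum(ot * yt / v) / sum(ot^2 / v)
    r2 <- sum((yt - mu * ot)^2 / v)
    # profile s2e = r2 / n
    0.5 * (n * log(r2 / n) + sum(log(v)))
  }
  opt <- optimize(nll, c(-12, 12))
  -opt$objective
}

#' Empirical-Bayes bandwidth selection for the Gaussian kernel
#'
#' Selects the bandwidth h from a grid by maximizing the marginal
#' likelihood of a single-kernel Gaussian-process model
#' y = mu 1 + g + e with g ~ N(0, s2g GK(h)), after profiling out mu and
#' the variance components.  Ties are broken toward the smaller h.  When
#' no phenotype is available the package convention is h = 1.
#'
#' @param X coded marker matrix (\code{\linkS4class{CodedMarkers}} or
#'   numeric matrix).
#' @param y complete phenotype vector aligned with the rows of \code{X}.
#' @param grid positive candidate bandwidths; default 13 log-spaced points
#'   on [0.01, 10].
#' @return the selected bandwidth (numeric scalar) with the per-grid
#'   log-marginal-likelihoods attached as attribute \code{"logLik"}.
#' @export
estimateBandwidth <- function(X, y,
                              grid = exp(seq(log(0.01), log(10),
                                             length.out = 13))) {
  stopifnot(length(grid) >= 1L, all(grid > 0), !anyNA(y))
  if (is(X, "CodedMarkers")) X <- X@values
  if (nrow(X) != length(y)) stop("y must align with the rows of X")
  grid <- sort(grid)
  D2 <- squaredDistanceMatrix(X)
  q <- median(D2[upper.tri(D2)])
  if (!is.finite(q) || q <= 0) stop("degenerate distances: q = 0")
  ll <- vapply(grid, function(h) {
    K <- exp(-h * D2 / q); diag(K) <- 1
    .kernelMarginalLogLik(K, y)
  }, numeric(1))
  if (all(!is.finite(ll)))
    stop("marginal likelihood non-finite for every grid bandwidth")
  h <- grid[which.max(ll)]   # which.max takes the first (smallest h) on ties
  attr(h, "logLik") <- stats::setNames(ll, signif(grid, 4))
  h
}

#' Build a genomic kernel from dosages in one call
#'
#' Convenience wrapper: codes the dosage matrix under the requested coding
#' and builds either the linear GBLUP matrix or the Gaussian kernel.  For
#' the Gaussian kernel, distances use the coded matrices as coded
#' (standardized for B, raw for A and C) unless \code{standardizeGK}
#' says otherwise.
#'
#' @param D a complete, MAF-filtered \code{\linkS4class{TetraDosage}}.
#' @param coding \code{"A"}, \code{"B"} or \code{"C"}.
#' @param method \code{"GB"} or \code{"GK"}.
#' @param h Gaussian bandwidth (default 1; see
#'   \code{\link{estimateBandwidth}}).
#' @param standardizeGK use the standardized coding-B matrix for GK
#'   distances when \code{coding = "B"} (default \code{TRUE}).
#' @return a \code{\linkS4class{GenomicKernel}}.
#' @export
makeKernel <- function(D, coding = c("B", "A", "C"),
                       method = c("GB", "GK"), h = 1,
                       standardizeGK = TRUE) {
  coding <- match.arg(coding)
  method <- match.arg(method)
  Xc <- switch(coding,
    A = codePseudoDiploid(D),
    B = codeAdditiveTetrasomic(D, standardize = (method == "GB" || standardizeGK)),
    C = codeFullTetraploid(D))
  if (method == "GB") {
    switch(coding,
      A = gbPseudoDiploid(Xc, alleleFreqs(D)),
      B = gbAdditive(Xc),
      C = gbFullTetraploid(Xc, quiet = TRUE))
  } else {
    gaussianKernel(Xc, h = h)
  }
}
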