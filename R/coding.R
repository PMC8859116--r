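#' Construct a tetraploid dosage matrix
#'
#' @param dosage numeric/integer matrix of B-allele counts in 0..4
#'   (NA = missing call), genotypes in rows.
#' @param genotypeIds,markerIds optional row/column labels; taken from
#'   dimnames when absent, generated (\code{G001...}, \code{M0001...})
#'   when neither is available.
#' @return a \code{\linkS4class{TetraDosage}} object.
#' @examples
#' D <- tetraDosage(matrix(c(0, 4, 2, 1), 2, 2))
#' dosageMatrix(D)
#' @export
tetraDosage <- function(dosage, genotypeIds = NULL, markerIds = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(genotypeIds))
    genotypeIds <- rownames(dosage)
  if (is.null(genotypeIds))
    genotypeIds <- sprintf("G%03d", seq_len(nrow(dosage)))
  if (is.null(markerIds))
    markerIds <- colnames(dosage)
  if (is.null(markerIds))
    markerIds <- sprintf("M%04d", seq_len(ncol(dosage)))
  dimnames(dosage) <- list(genotypeIds, markerIds)
  storage.mode(dosage) <- "integer"
  new("TetraDosage", dosage = dosage)
}

.assertComplete <- function(D, what) {
  if (anyNA(D@dosage))
    stop(what, " requires a complete dosage matrix; run imputeDosages() ",
         "first (", sum(is.na(D@dosage)), " missing calls present)")
}

#' Tetraploid allele frequencies from genotype-class counts
#'
#' Computes, per marker, the B-allele frequency
#' \deqn{p_i = (4 n_{bbbb} + 3 n_{abbb} + 2 n_{aabb} + n_{aaab}) / (4N)}
#' from the genotype-class tallies, which is identical to the mean dosage
#' divided by 4.
#'
#' @param D a complete \code{\linkS4class{TetraDosage}}.
#' @return an \code{\linkS4class{AlleleFreqs}} object.
#' @examples
#' D <- tetraDosage(matrix(c(4, 3, 2, 1), 4, 1))
#' alleleP(alleleFreqs(D))  # 10/16
#' @export
alleleFreqs <- function(D) {
  stopifnot(is(D, "TetraDosage"))
  .assertComplete(D, "alleleFreqs")
  X <- D@dosage
  counts <- t(apply(X, 2L, function(col) tabulate(col + 1L, nbins = 5L)))
  colnames(counts) <- c("n_aaaa", "n_aaab", "n_aabb", "n_abbb", "n_bbbb")
  rownames(counts) <- colnames(X)
  N <- nrow(X)
  p <- (4 * counts[, "n_bbbb"] + 3 * counts[, "n_abbb"] +
        2 * counts[, "n_aabb"] + counts[, "n_aaab"]) / (4 * N)
  new("AlleleFreqs", p = as.numeric(p), classCounts = counts)
}

#' Pseudo-diploid marker coding (A)
#'
#' Recodes tetraploid dosages to the pseudo-diploid scale: 0 for AAAA,
#' 2 for BBBB, 1 for any heterozygous class (AAAB, AABB, ABBB).  All
#' heterozygotes are assumed to sit at the midpoint of the homozygotes.
#'
#' @param D a complete \code{\linkS4class{TetraDosage}}.
#' @return a \code{\linkS4class{CodedMarkers}} with \code{coding = "A"};
#'   \code{columnFreqs} holds the tetraploid allele frequency p per marker.
#' @export
codePseudoDiploid <- function(D) {
  stopifnot(is(D, "TetraDosage"))
  .assertComplete(D, "codePseudoDiploid")
  X <- D@dosage
  A <- matrix(1, nrow(X), ncol(X), dimnames = dimnames(X))
  A[X == 0L] <- 0
  A[X == 4L] <- 2
  new("CodedMarkers", values = A, coding = "A", standardized = FALSE,
      columnFreqs = alleleP(alleleFreqs(D)))
}

#' Additive tetrasomic marker coding (B)
#'
#' Uses the allele dosage itself (0, 1, 2, 3, 4 for AAAA..BBBB) as the
#' additive code.  With \code{standardize = TRUE} each column is centered
#' and scaled to unit population variance (divide by N), so that the
#' cross-product relationship matrix XX'/M has average diagonal exactly 1.
#'
#' @param D a complete \code{\linkS4class{TetraDosage}}.
#' @param standardize standardize columns (default \code{TRUE}).
#' @return a \code{\linkS4class{CodedMarkers}} with \code{coding = "B"}.
#' @export
codeAdditiveTetrasomic <- function(D, standardize = TRUE) {
  stopifnot(is(D, "TetraDosage"))
  .assertComplete(D, "codeAdditiveTetrasomic")
  X <- D@dosage
  storage.mode(X) <- "double"
  p <- alleleP(alleleFreqs(D))
  if (standardize) {
    mu <- colMeans(X)
    s2 <- colMeans(X^2) - mu^2          # population variance
    if (any(s2 <= 0))
      stop("cannot standardize monomorphic marker(s): ",
           paste(colnames(X)[s2 <= 0], collapse = ", "),
           "; run filterMarkers() first")
    X <- sweep(sweep(X, 2L, mu, "-"), 2L, sqrt(s2), "/")
  }
  new("CodedMarkers", values = X, coding = "B", standardized = standardize,
      columnFreqs = p)
}

#' Full-tetraploid one-hot marker coding (C)
#'
#' Expands each marker into five indicator columns, one per genotype class
#' in the fixed order AAAA, AAAB, AABB, ABBB, BBBB, so that every genotype
#' class can carry its own (non-additive) effect.
#'
#' @param D a complete \code{\linkS4class{TetraDosage}}.
#' @return a \code{\linkS4class{CodedMarkers}} with \code{coding = "C"}
#'   (N x 5M); \code{columnFreqs} holds the observed genotype-class
#'   frequency of each indicator column.
#' @export
codeFullTetraploid <- function(D) {
  stopifnot(is(D, "TetraDosage"))
  .assertComplete(D, "codeFullTetraploid")
  X <- D@dosage
  n <- nrow(X); m <- ncol(X)
  classes <- c("AAAA", "AAAB", "AABB", "ABBB", "BBBB")
  C <- matrix(0, n, 5L * m)
  for (j in seq_len(m)) {
    cols <- (j - 1L) * 5L + X[, j] + 1L
    C[cbind(seq_len(n), cols)] <- 1
  }
  rownames(C) <- rownames(X)
  colnames(C) <- paste(rep(colnames(X), each = 5L), classes, sep = ".")
  new("CodedMarkers", values = C, coding = "C", standardized = FALSE,
      columnFreqs = colMeans(C))
}

#' Filter markers by minor-allele frequency
#'
#' Drops markers whose minor-allele frequency min(p, 1 - p) falls below a
#' threshold.  The relationship-matrix formulas divide by p(1 - p), so
#' monomorphic and near-monomorphic markers must be removed before kernel
#' construction.
#'
#' @param D a complete \code{\linkS4class{TetraDosage}}.
#' @param minMAF minimum minor-allele frequency in [0, 0.5); default 0.01.
#' @param quiet suppress the removal message.
#' @return the filtered \code{TetraDosage}.
#' @export
filterMarkers <- function(D, minMAF = 0.01, quiet = FALSE) {
  stopifnot(is(D, "TetraDosage"), minMAF >= 0, minMAF < 0.5)
  .assertComplete(D, "filterMarkers")
  p <- alleleP(alleleFreqs(D))
  keep <- pmin(p, 1 - p) >= minMAF
  if (!any(keep))
    stop("all ", length(p), " markers fall below minMAF = ", minMAF)
  if (!quiet && any(!keep))
    message("filterMarkers: removed ", sum(!keep), " of ", length(p),
            " markers with MAF < ", minMAF)
  tetraDosage(D@dosage[, keep, drop = FALSE])
}

#' Impute missing dosage calls
#'
#' Genotypes missing more than \code{maxMissing} of their marker calls are
#' dropped (mirroring the exclusion of lines lacking enough SNP data);
#' remaining missing calls are imputed per marker with the rounded
#' expected dosage, round(4 p), from the observed calls.
#'
#' @param D a \code{\linkS4class{TetraDosage}}, possibly with NAs.
#' @param maxMissing maximum tolerated fraction of missing calls per
#'   genotype (default 0.1).
#' @param quiet suppress the report message.
#' @return a complete \code{TetraDosage}.
#' @export
imputeDosages <- function(D, maxMissing = 0.1, quiet = FALSE) {
  stopifnot(is(D, "TetraDosage"), maxMissing >= 0, maxMissing <= 1)
  X <- D@dosage
  frac <- rowMeans(is.na(X))
  dropped <- rownames(X)[frac > maxMissing]
  if (length(dropped)) {
    if (length(dropped) >= nrow(X) - 1L)
      stop("imputeDosages would drop nearly all genotypes; check input")
    X <- X[frac <= maxMissing, , drop = FALSE]
  }
  nimp <- sum(is.na(X))
  if (nimp > 0L) {
    for (j in which(colSums(is.na(X)) > 0L)) {
      obs <- X[, j][!is.na(X[, j])]
      fill <- if (length(obs)) as.integer(round(mean(obs))) else 0L
      X[is.na(X[, j]), j] <- fill
    }
  }
  if (!quiet && (nimp > 0L || length(dropped)))
    message("imputeDosages: imputed ", nimp, " calls; dropped ",
            length(dropped), " genotypes",
            if (length(dropped)) paste0(" (", paste(dropped, collapse = ", "), ")"))
  tetraDosage(X)
}
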