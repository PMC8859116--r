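#' @rdname TetraDosage-class
#' @param object,x an object.
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' @rdname TetraDosage-class
#' @export
setGeneric("genotypeIds", function(x) standardGeneric("genotypeIds"))

#' @rdname TetraDosage-class
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname CodedMarkers-class
#' @param x an object.
#' @export
setGeneric("codedValues", function(x) standardGeneric("codedValues"))

#' @rdname CodedMarkers-class
#' @export
setGeneric("codingOf", function(x) standardGeneric("codingOf"))

#' @rdname GenomicKernel-class
#' @param x an object.
#' @export
setGeneric("kernelMatrix", function(x) standardGeneric("kernelMatrix"))

#' @rdname GxEFit-class
#' @param x an object.
#' @export
setGeneric("varianceComponents", function(x) standardGeneric("varianceComponents"))

#' @rdname GxEFit-class
#' @export
setGeneric("predictions", function(x) standardGeneric("predictions"))

## ---- TetraDosage ----

#' @rdname TetraDosage-class
#' @export
setMethod("dosageMatrix", "TetraDosage", function(x) x@dosage)

#' @rdname TetraDosage-class
#' @export
setMethod("genotypeIds", "TetraDosage", function(x) rownames(x@dosage))

#' @rdname TetraDosage-class
#' @export
setMethod("markerIds", "TetraDosage", function(x) colnames(x@dosage))

#' @rdname TetraDosage-class
#' @export
setMethod("dim", "TetraDosage", function(x) dim(x@dosage))

setMethod("show", "TetraDosage", function(object) {
  d <- object@dosage
  nmiss <- sum(is.na(d))
  cat("TetraDosage:", nrow(d), "genotypes x", ncol(d), "markers\n")
  cat("  dosage classes 0..4 (AAAA..BBBB);", nmiss, "missing calls\n")
})

## ---- CodedMarkers ----

#' @rdname CodedMarkers-class
#' @export
setMethod("codedValues", "CodedMarkers", function(x) x@values)

#' @rdname CodedMarkers-class
#' @export
setMethod("codingOf", "CodedMarkers", function(x) x@coding)

#' @rdname CodedMarkers-class
#' @export
setMethod("dim", "CodedMarkers", function(x) dim(x@values))

setMethod("show", "CodedMarkers", function(object) {
  cat("CodedMarkers: coding", object@coding,
      if (object@standardized) "(standardized)" else "(raw)", "\n")
  cat(" ", nrow(object@values), "genotypes x", ncol(object@values),
      "coded columns\n")
})

## ---- AlleleFreqs ----

#' @rdname AlleleFreqs-class
#' @param x an \code{AlleleFreqs} object.
#' @export
alleleP <- function(x) x@p

#' @rdname AlleleFreqs-class
#' @export
classCounts <- function(x) x@classCounts

setMethod("show", "AlleleFreqs", function(object) {
  cat("AlleleFreqs:", length(object@p), "markers, N =",
      sum(object@classCounts[1L, ]), "genotypes\n")
  cat("  p range:", paste(signif(range(object@p), 4), collapse = " .. "), "\n")
})

## ---- GenomicKernel ----

#' @rdname GenomicKernel-class
#' @export
setMethod("kernelMatrix", "GenomicKernel", function(x) x@kernel)

#' @rdname GenomicKernel-class
#' @export
setMethod("genotypeIds", "GenomicKernel", function(x) rownames(x@kernel))

#' @rdname GenomicKernel-class
#' @export
setMethod("dim", "GenomicKernel", function(x) dim(x@kernel))

setMethod("show", "GenomicKernel", function(object) {
  cat("GenomicKernel:", object@method, "from coding", object@coding, "-",
      nrow(object@kernel), "genotypes\n")
  if (object@method == "GK")
    cat("  bandwidth h =", object@bandwidth, ", q =",
        signif(object@qMedian, 6), "\n")
  cat("  mean diagonal:", signif(mean(diag(object@kernel)), 6), "\n")
})

## ---- GxEModel / GxEFit ----

setMethod("show", "GxEModel", function(object) {
  cat("GxEModel: model", object@modelId, "for trait", object@trait, "\n")
  cat(" ", sum(object@observed), "observed cells,",
      sum(!object@observed), "cells to predict\n")
  cat("  random components:",
      paste(vapply(object@components, `[[`, "", "label"), collapse = ", "),
      "+ residual\n")
})

#' @rdname GxEFit-class
#' @export
setMethod("varianceComponents", "GxEFit", function(x) x@variances)

#' Posterior predictions for masked cells
#'
#' Returns the posterior-mean prediction (intercept plus all random genetic
#' and environmental effects, excluding residual) for the cells whose
#' phenotype was missing/masked in the fitted model.
#'
#' @rdname GxEFit-class
#' @export
setMethod("predictions", "GxEFit", function(x) {
  out <- x@cells[!x@observed, , drop = FALSE]
  out$predicted <- x@fitted[!x@observed]
  out$sd <- x@predSd[!x@observed]
  rownames(out) <- NULL
  out
})

setMethod("show", "GxEFit", function(object) {
  cat("GxEFit: model", object@modelId, "for trait", object@trait, "\n")
  cat("  retained samples:", nrow(object@varTrace), "\n")
  cat("  posterior mean intercept:", signif(object@muMean, 6), "\n")
  v <- object@variances
  for (i in seq_len(nrow(v)))
    cat(sprintf("  sigma2[%s] = %.4g (sd %.3g)\n",
                v$component[i], v$mean[i], v$sd[i]))
})

setMethod("show", "CVPlan", function(object) {
  cat("CVPlan:", object@scheme, "-", length(object@masks), "replicates x",
      length(object@masks[[1L]]), "fold(s), seed", object@seed, "\n")
})
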