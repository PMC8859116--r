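#' Read and write dosage matrices
#'
#' The dosage dialect is a plain CSV: first column the genotype id, header
#' row of marker ids, integer cells 0-4; an empty cell is a missing call.
#' \code{writeDosage} emits the same dialect, so write-then-read is the
#' identity on values and ids.
#'
#' @param file path to a CSV file.
#' @return \code{readDosage}: a \code{\linkS4class{TetraDosage}}.
#' @export
readDosage <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("dosage file needs a genotype id column plus marker columns: ",
         file)
  ids <- as.character(df[[1L]])
  X <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(X) <- "double")
  bad <- which(!is.na(X) & (X != round(X) | X < 0 | X > 4), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("invalid dosage at row ", ids[bad[1L, 1L]], " (line ",
         bad[1L, 1L] + 1L, "), marker ", colnames(X)[bad[1L, 2L]],
         ": values must be integers 0-4")
  tetraDosage(X, genotypeIds = ids)
}

#' @rdname readDosage
#' @param D a \code{\linkS4class{TetraDosage}}.
#' @export
writeDosage <- function(D, file) {
  stopifnot(is(D, "TetraDosage"))
  X <- dosageMatrix(D)
  df <- data.frame(genotype_id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' Read and write long-format phenotype tables
#'
#' Columns \code{genotype_id}, \code{environment_id}, \code{trait},
#' \code{value}; an empty value cell is a missing phenotype.  Duplicate
#' (genotype, environment, trait) cells are a parse error.
#'
#' @param file path to a CSV file.
#' @return \code{readPhenotypes}: a data.frame in the long dialect.
#' @export
readPhenotypes <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("genotype_id", "environment_id", "trait", "value")
  if (!all(need %in% names(df)))
    stop("phenotype file must have columns ",
         paste(need, collapse = ", "), ": ", file)
  key <- paste(df$genotype_id, df$environment_id, df$trait)
  if (anyDuplicated(key)) {
    first <- which(duplicated(key))[1L]
    stop("duplicate phenotype cell at line ", first + 1L, ": (",
         df$genotype_id[first], ", ", df$environment_id[first], ", ",
         df$trait[first], ")")
  }
  df$value <- suppressWarnings(as.numeric(df$value))
  df[need]
}

#' @rdname readPhenotypes
#' @param pheno a long-format phenotype data.frame.
#' @export
writePhenotypes <- function(pheno, file) {
  utils::write.csv(
    pheno[c("genotype_id", "environment_id", "trait", "value")],
    file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' Read and write genomic kernels
#'
#' A kernel is stored as a square CSV (genotype ids as header and first
#' column) plus a plain key-value sidecar \code{<file>.meta} holding the
#' provenance (method, coding, bandwidth, q).
#'
#' @param file path to the kernel CSV.
#' @return \code{readKernel}: a \code{\linkS4class{GenomicKernel}}.
#' @export
readKernel <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  K <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(K) <- "double"
  dimnames(K) <- list(ids, colnames(K))
  meta <- c(method = "GB", coding = "B",
            bandwidth = NA_character_, q = NA_character_)
  metaFile <- paste0(file, ".meta")
  if (file.exists(metaFile)) {
    kv <- utils::read.table(metaFile, sep = "=", strip.white = TRUE,
                            stringsAsFactors = FALSE,
                            col.names = c("key", "value"))
    meta[kv$key] <- kv$value
  }
  new("GenomicKernel", kernel = (K + t(K)) / 2,
      method = meta[["method"]], coding = meta[["coding"]],
      bandwidth = as.numeric(meta[["bandwidth"]]),
      qMedian = as.numeric(meta[["q"]]))
}

#' @rdname readKernel
#' @param K a \code{\linkS4class{GenomicKernel}}.
#' @export
writeKernel <- function(K, file) {
  stopifnot(is(K, "GenomicKernel"))
  M <- kernelMatrix(K)
  df <- data.frame(genotype_id = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  writeLines(c(paste0("method=", K@method),
               paste0("coding=", K@coding),
               paste0("bandwidth=", K@bandwidth),
               paste0("q=", K@qMedian)),
             paste0(file, ".meta"))
  invisible(file)
}
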