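.defaultConfig <- function() {
  list(trait = NULL, coding = "B", method = "GB", model = 1L,
       min_maf = 0.01, bandwidth = 1,
       cv = list(n_reps = 30L, train_frac = 0.7, n_folds = 4L),
       mcmc = list(n_iter = 30000L, burn_in = 5000L, thin = 2L,
                   prior_df = 5, prior_r2 = 0.5),
       seed = 1L)
}

.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(user[[nm]]) && is.list(base[[nm]]))
      .mergeConfig(base[[nm]], user[[nm]]) else user[[nm]]
  }
  base
}

#' Validate a pipeline configuration
#'
#' Checks the coding/model/method combination before any compute: coding
#' \code{"BC"} (two kernels) requires the two-kernel models 2 or 4, and
#' the multi-environment models 3-4 require at least two environments in
#' the phenotype table.
#'
#' @param cfg configuration list (see \code{\link{runPipeline}}).
#' @param nEnvironments number of environments present in the phenotypes.
#' @return the validated config, invisibly; errors on invalid combos.
#' @export
validateRunConfig <- function(cfg, nEnvironments) {
  if (!cfg$coding %in% c("A", "B", "C", "BC"))
    stop("coding must be one of A, B, C, BC")
  if (!cfg$method %in% c("GB", "GK")) stop("method must be GB or GK")
  if (!cfg$model %in% 1:4) stop("model must be 1, 2, 3 or 4")
  if (cfg$coding == "BC" && !cfg$model %in% c(2L, 4L))
    stop("coding BC (two kernels) requires model 2 or 4")
  if (cfg$model %in% c(2L, 4L) && cfg$coding != "BC")
    stop("models 2 and 4 are two-kernel models; use coding = 'BC'")
  if (cfg$model %in% c(3L, 4L) && nEnvironments < 2L)
    stop("models 3 and 4 need at least 2 environments; found ",
         nEnvironments)
  if (cfg$model %in% c(1L, 2L) && nEnvironments != 1L)
    stop("models 1 and 2 are single-environment; subset the phenotype ",
         "table to one environment first (found ", nEnvironments, ")")
  invisible(cfg)
}

#' Run the full genomic prediction pipeline
#'
#' Composes the whole workflow from files on disk: read dosages and
#' phenotypes, impute and MAF-filter, build the requested kernel(s), run
#' the matching cross-validation scheme (random train/test partitions for
#' models 1-2, CV2 folds for models 3-4), and write kernels, per-
#' replicate and summary accuracy CSVs, a log and a machine-readable
#' manifest into the output directory.  Deterministic given the seed.
#'
#' @param config a configuration list or path to a YAML file with keys
#'   \code{dosage_file}, \code{phenotype_file}, \code{output_dir},
#'   \code{trait}, \code{coding} (A|B|C|BC), \code{method} (GB|GK),
#'   \code{model} (1-4), \code{min_maf}, \code{bandwidth}, \code{seed},
#'   and nested \code{cv} (n_reps, train_frac, n_folds) and \code{mcmc}
#'   (n_iter, burn_in, thin, prior_df, prior_r2) blocks.  Unspecified
#'   keys take the defaults above.
#' @param ... individual keys overriding the config file values.
#' @return invisibly, a list with the CV summary, the manifest, and the
#'   paths written.
#' @export
runPipeline <- function(config, ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(.defaultConfig(), config)
  cfg <- .mergeConfig(cfg, list(...))
  cfg$model <- as.integer(cfg$model)
  for (k in c("dosage_file", "phenotype_file", "output_dir"))
    if (is.null(cfg[[k]])) stop("config key '", k, "' is required")

  pheno <- readPhenotypes(cfg$phenotype_file)
  if (is.null(cfg$trait)) cfg$trait <- pheno$trait[1L]
  pheno <- pheno[pheno$trait == cfg$trait, , drop = FALSE]
  envs <- unique(pheno$environment_id)
  validateRunConfig(cfg, length(envs))

  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(cfg$output_dir, "pipeline.log")
  logLines <- c(paste0("tetraGP ",
                       as.character(utils::packageVersion("tetraGP"))),
                paste0("R ", getRversion()),
                paste0("seed: ", cfg$seed),
                paste0("trait: ", cfg$trait),
                paste0("model: ", cfg$model, ", coding: ", cfg$coding,
                       ", method: ", cfg$method))

  D <- readDosage(cfg$dosage_file)
  nRaw <- nrow(dosageMatrix(D))
  msgs <- character()
  withCallingHandlers({
    D <- imputeDosages(D)
    D <- filterMarkers(D, minMAF = cfg$min_maf)
  }, message = function(m) {
    msgs <<- c(msgs, conditionMessage(m))
    invokeRestart("muffleMessage")
  })
  logLines <- c(logLines, trimws(msgs),
                paste0("genotypes: ", nRaw, " read, ",
                       nrow(dosageMatrix(D)), " kept; markers kept: ",
                       ncol(dosageMatrix(D))))

  pheno <- pheno[pheno$genotype_id %in% genotypeIds(D), , drop = FALSE]

  codings <- if (cfg$coding == "BC") c("B", "C") else cfg$coding
  kernels <- lapply(codings, function(cd)
    makeKernel(D, coding = cd, method = cfg$method, h = cfg$bandwidth))
  kernelPaths <- vapply(seq_along(kernels), function(i) {
    path <- file.path(cfg$output_dir,
                      sprintf("kernel_%s_%s.csv", cfg$method, codings[i]))
    writeKernel(kernels[[i]], path)
  }, character(1))

  single <- cfg$model %in% c(1L, 2L)
  plan <- if (single) {
    obsIds <- unique(pheno$genotype_id[!is.na(pheno$value)])
    singleEnvPartitions(obsIds, nReps = cfg$cv$n_reps,
                        trainFrac = cfg$cv$train_frac, seed = cfg$seed)
  } else {
    obsCells <- pheno[!is.na(pheno$value),
                      c("genotype_id", "environment_id")]
    cv2Folds(obsCells, nFolds = cfg$cv$n_folds,
             nReps = cfg$cv$n_reps, seed = cfg$seed)
  }

  cvRes <- runCrossValidation(pheno, cfg$trait, kernels, cfg$model, plan,
                              nIter = cfg$mcmc$n_iter,
                              burnIn = cfg$mcmc$burn_in,
                              thin = cfg$mcmc$thin,
                              priorDf = cfg$mcmc$prior_df,
                              priorR2 = cfg$mcmc$prior_r2,
                              seed = cfg$seed)

  meta <- data.frame(trait = cfg$trait, model = cfg$model,
                     coding = cfg$coding, method = cfg$method)
  resPath <- file.path(cfg$output_dir, "cv_results.csv")
  utils::write.csv(cbind(meta, cvRes$results), resPath, row.names = FALSE,
                   quote = FALSE)
  sumPath <- file.path(cfg$output_dir, "cv_summary.csv")
  utils::write.csv(cbind(meta, cvRes$summary), sumPath, row.names = FALSE,
                   quote = FALSE)

  manifest <- list(config = cfg,
                   n_genotypes = nrow(dosageMatrix(D)),
                   n_markers = ncol(dosageMatrix(D)),
                   environments = as.list(envs),
                   outputs = list(kernels = as.list(kernelPaths),
                                  results = resPath, summary = sumPath))
  manPath <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manPath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  writeLines(logLines, logFile)

  invisible(list(summary = cvRes$summary, results = cvRes$results,
                 manifest = manifest,
                 paths = list(results = resPath, summary = sumPath,
                              manifest = manPath, log = logFile,
                              kernels = kernelPaths)))
}
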