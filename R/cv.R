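#' Random train/test partitions for single-environment validation
#'
#' Draws independent random splits of the genotypes of one environment
#' into a training fraction and a testing remainder (the default 30
#' replicates of 70/30 splits).
#'
#' @param ids genotype ids (or an integer count, expanded to indices).
#' @param nReps number of random partitions (default 30).
#' @param trainFrac training fraction in (0, 1) (default 0.7).
#' @param seed integer seed; the plan is reproducible from it.
#' @return a \code{\linkS4class{CVPlan}} whose masks hold the test ids of
#'   each replicate.
#' @export
singleEnvPartitions <- function(ids, nReps = 30L, trainFrac = 0.7,
                                seed = 1L) {
  if (length(ids) == 1L && is.numeric(ids)) ids <- seq_len(ids)
  ids <- as.character(ids)
  n <- length(ids)
  stopifnot(trainFrac > 0, trainFrac < 1, n >= 4L, nReps >= 1L)
  nTrain <- round(trainFrac * n)
  if (nTrain == 0L || nTrain == n)
    stop("train or test set empty with n = ", n,
         " and trainFrac = ", trainFrac)
  set.seed(as.integer(seed))
  masks <- lapply(seq_len(nReps), function(i) {
    list(test = sort(sample(ids, n - nTrain)))
  })
  new("CVPlan", scheme = "single_env_random", masks = masks,
      cells = data.frame(), seed = as.integer(seed),
      params = list(n = n, nReps = nReps, trainFrac = trainFrac))
}

#' CV2 fold masks for multi-environment validation
#'
#' Builds replicated random fold partitions under the CV2 scheme:
#' a line is predicted in one site while its records at the other sites
#' remain in training.  Only cells of lines observed in at least two
#' environments are eligible for masking, and within every replicate each
#' line's eligible cells are spread over distinct folds, so no fold ever
#' removes all environments of a line.  Lines observed in a single
#' environment are never masked.
#'
#' @param cells data.frame of observed cells with columns
#'   \code{genotype_id} and \code{environment_id}.
#' @param nFolds folds per replicate (default 4).
#' @param nReps independent replicates (default 10).
#' @param seed integer seed.
#' @return a \code{\linkS4class{CVPlan}}; masks are row indices into
#'   \code{cells}.
#' @export
cv2Folds <- function(cells, nFolds = 4L, nReps = 10L, seed = 1L) {
  stopifnot(all(c("genotype_id", "environment_id") %in% names(cells)),
            nFolds >= 2L, nReps >= 1L)
  cells <- as.data.frame(cells)
  gid <- as.character(cells$genotype_id)
  nEnv <- table(gid)
  eligible <- which(nEnv[gid] >= 2L)
  if (length(eligible) == 0L)
    stop("CV2 infeasible: no line is observed in 2 or more environments")
  set.seed(as.integer(seed))
  masks <- lapply(seq_len(nReps), function(r) {
    fold <- integer(nrow(cells))
    for (g in unique(gid[eligible])) {
      rows <- which(gid == g)
      k <- length(rows)
      f <- if (k <= nFolds) sample(nFolds, k)        # distinct folds
           else c(sample(nFolds), sample(nFolds, k - nFolds, replace = TRUE))
      fold[rows] <- f
    }
    lapply(seq_len(nFolds), function(f) which(fold == f))
  })
  new("CVPlan", scheme = "CV2", masks = masks, cells = cells,
      seed = as.integer(seed),
      params = list(nFolds = nFolds, nReps = nReps))
}

#' Predictive accuracy as Pearson correlation
#'
#' Correlates predicted with observed values, optionally within
#' environment.  Groups with fewer than 3 points or zero variance in
#' either vector yield \code{NA} with a warning rather than an error.
#'
#' @param pred,obs numeric vectors of equal length.
#' @param environment optional grouping factor (environment per value).
#' @return a data.frame with columns \code{environment} (or \code{"all"})
#'   and \code{correlation}.
#' @export
accuracy <- function(pred, obs, environment = NULL) {
  stopifnot(length(pred) == length(obs))
  if (is.null(environment)) environment <- rep("all", length(pred))
  groups <- split(seq_along(pred), as.character(environment))
  out <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    r <- if (length(i) < 3L) {
      warning("accuracy: group '", g, "' has fewer than 3 points; NA")
      NA_real_
    } else if (sd(pred[i]) == 0 || sd(obs[i]) == 0) {
      warning("accuracy: zero variance in group '", g, "'; NA")
      NA_real_
    } else cor(pred[i], obs[i])
    data.frame(environment = g, correlation = r, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Standardized selection intensity under truncation selection
#'
#' i = phi(z) / alpha, where alpha is the selected fraction and z the
#' standard-normal quantile with upper-tail probability alpha.  Selecting
#' the top 3\% of a normal distribution gives i = 2.268.
#'
#' @param fraction selected fraction in (0, 1).
#' @return the selection intensity (positive scalar).
#' @examples
#' round(selectionIntensity(0.03), 3)  # 2.268
#' @export
selectionIntensity <- function(fraction) {
  if (any(fraction <= 0 | fraction >= 1))
    stop("fraction must lie strictly between 0 and 1")
  dnorm(qnorm(1 - fraction)) / fraction
}

#' Select the top fraction of genotypes by genomic value
#'
#' Returns the ceiling(fraction * N) genotypes with the highest
#' genomic-estimated breeding values; ties are broken by genotype id
#' order, so the selection is reproducible.
#'
#' @param gebv named numeric vector of posterior-mean genetic values.
#' @param fraction selected fraction in (0, 1) (default 0.03).
#' @return character vector of selected genotype ids, best first.
#' @export
selectTop <- function(gebv, fraction = 0.03) {
  stopifnot(all(is.finite(gebv)), fraction > 0, fraction < 1)
  if (is.null(names(gebv)))
    names(gebv) <- sprintf("G%03d", seq_along(gebv))
  k <- ceiling(fraction * length(gebv))
  ord <- order(-gebv, names(gebv))
  names(gebv)[ord][seq_len(k)]
}

#' Run a cross-validation experiment
#'
#' Executes a \code{\linkS4class{CVPlan}} against phenotypes and kernels:
#' for each replicate (and fold, under CV2) the test cells are masked,
#' the model is rebuilt and refitted by Gibbs sampling, the masked cells
#' are predicted, and the predictive Pearson correlation is computed --
#' per environment for multi-environment fits.
#'
#' @param pheno long-format phenotype table (see \code{\link{buildModel}}).
#' @param trait trait to validate.
#' @param kernels kernel or list of kernels matching \code{modelId}.
#' @param modelId 1-4.
#' @param plan a \code{\linkS4class{CVPlan}} (scheme
#'   \code{single_env_random} for models 1-2, \code{CV2} for models 3-4).
#' @param nIter,burnIn,thin,priorDf,priorR2 MCMC settings passed to
#'   \code{\link{fitGibbs}}.
#' @param seed base seed; replicate r / fold f uses a deterministic
#'   offset of it.
#' @return list with \code{results} (one row per replicate/fold/
#'   environment with the test-set correlation) and \code{summary}
#'   (mean and sd of the correlation per environment).
#' @export
runCrossValidation <- function(pheno, trait, kernels, modelId, plan,
                               nIter = 30000L, burnIn = 5000L, thin = 2L,
                               priorDf = 5, priorR2 = 0.5, seed = 1L) {
  stopifnot(is(plan, "CVPlan"))
  modelId <- as.integer(modelId)
  single <- plan@scheme == "single_env_random"
  if (single && !modelId %in% c(1L, 2L))
    stop("single_env_random plans go with models 1-2")
  if (!single && !modelId %in% c(3L, 4L))
    stop("CV2 plans go with models 3-4")
  ph <- pheno[pheno$trait == trait, , drop = FALSE]
  rows <- list()
  for (r in seq_along(plan@masks)) {
    folds <- if (single) plan@masks[[r]]["test"] else plan@masks[[r]]
    for (f in seq_along(folds)) {
      masked <- ph
      if (single) {
        testIds <- folds[[f]]
        hold <- masked$genotype_id %in% testIds & !is.na(masked$value)
      } else {
        cellKey <- paste(plan@cells$genotype_id[folds[[f]]],
                         plan@cells$environment_id[folds[[f]]])
        hold <- paste(masked$genotype_id, masked$environment_id) %in% cellKey
      }
      if (!any(hold)) next
      truth <- masked$value[hold]
      masked$value[hold] <- NA
      model <- buildModel(masked, trait, kernels, modelId)
      fit <- fitGibbs(model, nIter = nIter, burnIn = burnIn, thin = thin,
                      seed = seed + 1000L * r + f,
                      priorDf = priorDf, priorR2 = priorR2)
      pred <- predict(fit, masked[hold, c("genotype_id", "environment_id")])
      acc <- accuracy(pred$predicted, truth,
                      environment = if (single) NULL else
                        masked$environment_id[hold])
      acc$replicate <- r
      acc$fold <- f
      rows[[length(rows) + 1L]] <- acc
    }
  }
  results <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(results, results$environment),
    function(d) data.frame(environment = d$environment[1L],
                           mean = mean(d$correlation, na.rm = TRUE),
                           sd = sd(d$correlation, na.rm = TRUE),
                           n = sum(is.finite(d$correlation)),
                           stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  list(results = results, summary = summ)
}
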