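## Eigendecompose a covariance structure over all cells, restricted to the
## observed rows, and precompute the conditional-mean projector for the
## cells to predict:
##   u_obs = U b,  b_j ~ N(0, sigma2 d_j)
##   E[u_pred | u_obs] = Sigma[pred, obs] pinv(Sigma[obs, obs]) u_obs
##                     = (Sigma[pred, obs] U diag(1/d)) b
.eigenComponent <- function(Sigma, obs, label) {
  So <- Sigma[obs, obs, drop = FALSE]
  eg <- eigen(So, symmetric = TRUE)
  tol <- 1e-8 * max(eg$values, 1e-12)
  keep <- eg$values > tol
  if (!any(keep))
    stop("covariance component '", label, "' has no positive eigenvalues")
  U <- eg$vectors[, keep, drop = FALSE]
  d <- eg$values[keep]
  if (any(!obs)) {
    Spo <- Sigma[!obs, obs, drop = FALSE]
    P <- (Spo %*% U) %*% diag(1 / d, nrow = length(d))
  } else {
    P <- matrix(0, 0L, length(d))
  }
  list(label = label, U = U, d = d, P = P,
       meanDiag = mean(diag(So)))
}

.hadamard <- function(A, B) A * B

#' Assemble a Bayesian genomic prediction model
#'
#' Builds the observation-level covariance structures for one of the four
#' kernel regression models and eigendecomposes each random component:
#' \describe{
#'   \item{Model 1}{single environment, one kernel:
#'     y = mu 1 + Z g + e.}
#'   \item{Model 2}{single environment, two kernels (additive B +
#'     non-additive C): y = mu 1 + Z g1 + Z g2 + e.}
#'   \item{Model 3}{multi-environment with G x E, one kernel:
#'     y = mu 1 + Z1 env + Z2 g + ge + e, where the interaction
#'     covariance is the Hadamard product (Z1 E Z1') * (Z2 K Z2').}
#'   \item{Model 4}{multi-environment, two kernels, each with its own
#'     Hadamard-product interaction term.}
#' }
#' Environments are random with covariance E (identity by default).
#' Phenotype rows with \code{NA} value are treated as cells to predict:
#' they contribute nothing to the likelihood, and their predictions are
#' formed from the conditional mean of each random effect given the
#' training cells.
#'
#' @param pheno long-format phenotype data.frame with columns
#'   \code{genotype_id}, \code{environment_id}, \code{trait},
#'   \code{value} (NA = cell to predict).
#' @param trait trait name to model.
#' @param kernels a \code{\linkS4class{GenomicKernel}} or list of one
#'   (models 1, 3) or two (models 2, 4) kernels.
#' @param modelId 1, 2, 3 or 4.
#' @param E environment covariance matrix (default identity over the
#'   observed environments).
#' @return a \code{\linkS4class{GxEModel}}.
#' @export
buildModel <- function(pheno, trait, kernels, modelId, E = NULL) {
  modelId <- as.integer(modelId)
  stopifnot(modelId %in% 1:4)
  if (is(kernels, "GenomicKernel")) kernels <- list(kernels)
  needK <- if (modelId %in% c(1L, 3L)) 1L else 2L
  if (length(kernels) != needK)
    stop("model ", modelId, " needs ", needK, " kernel(s), got ",
         length(kernels))

  ph <- pheno[pheno$trait == trait, , drop = FALSE]
  if (nrow(ph) == 0L) stop("no phenotype rows for trait '", trait, "'")
  key <- paste(ph$genotype_id, ph$environment_id)
  if (anyDuplicated(key))
    stop("duplicate (genotype, environment) cells for trait '", trait, "'")
  envs <- sort(unique(as.character(ph$environment_id)))
  if (modelId %in% c(1L, 2L) && length(envs) != 1L)
    stop("models 1 and 2 are single-environment; found ",
         length(envs), " environments")
  if (modelId %in% c(3L, 4L) && length(envs) < 2L)
    stop("models 3 and 4 need at least 2 environments")
  obs <- !is.na(ph$value)
  if (!any(obs)) stop("no observed phenotype values")

  gids <- as.character(ph$genotype_id)
  for (K in kernels) {
    missing <- setdiff(unique(gids), genotypeIds(K))
    if (length(missing))
      stop("genotypes absent from kernel: ",
           paste(missing, collapse = ", "))
  }
  if (is.null(E)) {
    E <- diag(length(envs))
    dimnames(E) <- list(envs, envs)
  } else {
    if (is.null(rownames(E))) dimnames(E) <- list(envs, envs)
    E <- E[envs, envs, drop = FALSE]
  }

  eidx <- match(as.character(ph$environment_id), envs)
  ZEZ <- E[eidx, eidx, drop = FALSE]          # Z1 E Z1'
  ZKZ <- lapply(kernels, function(K)
    kernelMatrix(K)[gids, gids, drop = FALSE]) # Z2 K Z2'

  comps <- list()
  if (modelId %in% c(3L, 4L))
    comps <- c(comps, list(.eigenComponent(ZEZ, obs, "env")))
  glabels <- if (needK == 1L) "g" else c("g1", "g2")
  for (i in seq_len(needK)) {
    comps <- c(comps, list(.eigenComponent(ZKZ[[i]], obs, glabels[i])))
    if (modelId %in% c(3L, 4L)) {
      ilab <- if (needK == 1L) "gxe" else paste0(glabels[i], "xe")
      comps <- c(comps,
                 list(.eigenComponent(.hadamard(ZEZ, ZKZ[[i]]), obs, ilab)))
    }
  }

  cells <- data.frame(genotype_id = gids,
                      environment_id = as.character(ph$environment_id),
                      stringsAsFactors = FALSE)
  new("GxEModel", y = as.numeric(ph$value), cells = cells, observed = obs,
      components = comps, modelId = modelId, trait = as.character(trait))
}

#' Fit an assembled model by Gibbs sampling
#'
#' Samples the intercept (flat prior), every random-effect vector (in the
#' eigenbasis of its covariance component, giving diagonal full
#' conditionals) and the variance components (scaled-inverse-chi-square
#' full conditionals).  Priors are weakly informative scaled-inverse-
#' chi-square with \code{priorDf} degrees of freedom; the prior modes
#' split \code{priorR2} of the phenotypic variance equally among the
#' random components (each standardized by its mean covariance diagonal),
#' with the remainder on the residual.
#'
#' @param model a \code{\linkS4class{GxEModel}} from
#'   \code{\link{buildModel}}.
#' @param nIter total iterations (default 30000).
#' @param burnIn discarded initial iterations (default 5000).
#' @param thin thinning interval (default 2).
#' @param seed integer seed; fixing it makes all posterior summaries
#'   reproducible bit-for-bit.
#' @param priorDf prior degrees of freedom for every variance (default 5).
#' @param priorR2 prior fraction of phenotypic variance assigned to the
#'   random components jointly (default 0.5).
#' @param fixVariances optional named numeric vector fixing some variance
#'   components instead of sampling them; names are component labels
#'   (\code{"g"}, \code{"gxe"}, ...) plus \code{"residual"}.
#' @param traceEffects keep full traces of the observation-level effects
#'   (memory-hungry; intended for small problems/diagnostics).
#' @return a \code{\linkS4class{GxEFit}}.
#' @export
fitGibbs <- function(model, nIter = 30000L, burnIn = 5000L, thin = 2L,
                     seed = 1L, priorDf = 5, priorR2 = 0.5,
                     fixVariances = NULL, traceEffects = FALSE) {
  stopifnot(is(model, "GxEModel"))
  nIter <- as.integer(nIter); burnIn <- as.integer(burnIn)
  thin <- as.integer(thin)
  if (burnIn >= nIter) stop("burnIn must be smaller than nIter")
  if (thin < 1L) stop("thin must be >= 1")
  if ((nIter - burnIn) / thin < 100)
    stop("fewer than 100 retained samples; increase nIter or reduce thin")
  if (priorR2 <= 0 || priorR2 >= 1) stop("priorR2 must be in (0, 1)")

  obs <- model@observed
  y <- model@y[obs]
  varY <- var(y)
  if (!is.finite(varY) || varY <= 0) varY <- 1
  nc <- length(model@components)
  modeFactor <- (priorDf + 2) / priorDf  # scale giving the wanted prior mode

  fixed <- rep(NA_real_, nc)
  labels <- vapply(model@components, `[[`, "", "label")
  if (!is.null(fixVariances)) {
    bad <- setdiff(names(fixVariances), c(labels, "residual"))
    if (length(bad))
      stop("unknown component(s) in fixVariances: ",
           paste(bad, collapse = ", "))
    m <- match(labels, names(fixVariances))
    fixed <- as.numeric(fixVariances[m])
  }
  residFixed <- if (!is.null(fixVariances) &&
                    "residual" %in% names(fixVariances))
    as.numeric(fixVariances[["residual"]]) else NA_real_

  comps <- lapply(seq_len(nc), function(i) {
    cmp <- model@components[[i]]
    cmp$priorScale <- varY * priorR2 / nc / cmp$meanDiag * modeFactor
    cmp$fixed <- fixed[i]
    cmp
  })
  residScale <- varY * (1 - priorR2) * modeFactor

  set.seed(as.integer(seed))
  res <- .gibbs_gxe(y, comps, nIter, burnIn, thin,
                    priorDf, residScale, residFixed, traceEffects)

  vt <- res$varTrace
  colnames(vt) <- c(labels, "residual", "mu")
  vdf <- data.frame(component = c(labels, "residual"),
                    mean = apply(vt[, seq_len(nc + 1L), drop = FALSE], 2L, mean),
                    sd = apply(vt[, seq_len(nc + 1L), drop = FALSE], 2L, sd),
                    median = apply(vt[, seq_len(nc + 1L), drop = FALSE], 2L,
                                   median),
                    stringsAsFactors = FALSE)
  rownames(vdf) <- NULL

  fitted <- numeric(length(model@y))
  fitted[obs] <- res$fittedMean
  predSd <- numeric(length(model@y))
  predSd[obs] <- res$fittedSd
  if (any(!obs)) {
    fitted[!obs] <- res$predMean
    predSd[!obs] <- res$predSd
  }
  effects <- res$effects
  names(effects) <- labels
  effTraces <- if (traceEffects) {
    tr <- res$effectTraces
    names(tr) <- labels
    tr
  } else list()

  new("GxEFit",
      muMean = mean(vt[, "mu"]), muSd = sd(vt[, "mu"]),
      variances = vdf, varTrace = vt,
      effects = effects, effectTraces = effTraces,
      cells = model@cells, observed = obs,
      fitted = fitted, predSd = predSd,
      config = list(nIter = nIter, burnIn = burnIn, thin = thin,
                    seed = as.integer(seed), priorDf = priorDf,
                    priorR2 = priorR2),
      modelId = model@modelId, trait = model@trait)
}

#' Predictions for specific cells
#'
#' Looks up the posterior-mean prediction (intercept + environment +
#' genetic + interaction effects, no residual) for the requested
#' (genotype, environment) cells of a fitted model.
#'
#' @param object a \code{\linkS4class{GxEFit}}.
#' @param cells data.frame with columns \code{genotype_id} and
#'   \code{environment_id}; defaults to all masked cells.
#' @param ... ignored.
#' @return \code{cells} with a \code{predicted} column appended.
#' @export
setMethod("predict", "GxEFit", function(object, cells = NULL, ...) {
  if (is.null(cells)) return(predictions(object))
  stopifnot(all(c("genotype_id", "environment_id") %in% names(cells)))
  key <- paste(object@cells$genotype_id, object@cells$environment_id)
  want <- paste(cells$genotype_id, cells$environment_id)
  idx <- match(want, key)
  if (anyNA(idx)) {
    unknown <- cells$genotype_id[is.na(idx)]
    stop("cells not part of the fitted model (genotypes: ",
         paste(unique(unknown), collapse = ", "), ")")
  }
  out <- cells
  out$predicted <- object@fitted[idx]
  out
})
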