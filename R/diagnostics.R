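## Effective sample size via Geyer's initial-positive-sequence estimator:
## ess = n / (1 + 2 sum(rho_k)), summing autocorrelations while the paired
## sums rho_{2k} + rho_{2k+1} stay positive.
.ess <- function(x) {
  n <- length(x)
  if (n < 4L || sd(x) == 0) return(NA_real_)
  x <- x - mean(x)
  ac <- stats::acf(x, lag.max = min(n - 2L, 10L * ceiling(sqrt(n))),
                   plot = FALSE, demean = FALSE)$acf[, 1L, 1L]
  s <- 0
  k <- 2L
  while (k + 1L <= length(ac)) {
    pair <- ac[k] + ac[k + 1L]
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2L
  }
  min(n, n / (1 + 2 * s))
}

## Geweke convergence z-score: standardized difference between the means
## of the first 10% and last 50% of the chain, with ESS-adjusted variances.
.geweke <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  if (n < 20L || sd(x) == 0) return(NA_real_)
  a <- x[seq_len(max(2L, floor(frac1 * n)))]
  b <- x[seq.int(n - floor(frac2 * n) + 1L, n)]
  va <- var(a) / max(.ess(a), 1)
  vb <- var(b) / max(.ess(b), 1)
  if (!is.finite(va + vb) || va + vb == 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(va + vb)
}

#' MCMC convergence diagnostics
#'
#' Effective sample size (initial-positive-sequence autocorrelation
#' estimator) and a Geweke-style z-score (first 10\% vs last 50\% of the
#' chain) for every retained trace of a fitted model.  A parameter is
#' flagged when |z| > 2 or ESS < 100; constant (degenerate) traces are
#' flagged, not an error.
#'
#' @param fitted a \code{\linkS4class{GxEFit}}, or a numeric matrix of
#'   traces (samples in rows).
#' @return data.frame with columns \code{parameter}, \code{ess},
#'   \code{geweke_z}, \code{flagged}, \code{degenerate}.
#' @export
mcmcDiagnostics <- function(fitted) {
  tr <- if (is(fitted, "GxEFit")) fitted@varTrace else as.matrix(fitted)
  if (is.null(colnames(tr)))
    colnames(tr) <- paste0("par", seq_len(ncol(tr)))
  out <- do.call(rbind, lapply(colnames(tr), function(nm) {
    x <- tr[, nm]
    degen <- sd(x) == 0
    ess <- if (degen) 0 else .ess(x)
    z <- if (degen) NA_real_ else .geweke(x)
    data.frame(parameter = nm, ess = ess, geweke_z = z,
               flagged = degen || (is.finite(ess) && ess < 100) ||
                 (is.finite(z) && abs(z) > 2),
               degenerate = degen, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
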