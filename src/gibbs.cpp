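// Gibbs sampler for Bayesian kernel regression with several random
// components, each supplied in the eigenbasis of its covariance
// structure: u_c = U_c b_c with b_cj ~ N(0, sigma2_c * d_cj).  Working in
// the eigenbasis makes every full conditional diagonal, which is what
// keeps 30,000-iteration chains tractable at hundreds of observations.
//
// Uses R's RNG throughout so results are reproducible from set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// comps: list of lists with elements
//   U (n_obs x k), d (k), P (n_pred x k, possibly 0-row), priorScale,
//   fixed (NA or fixed variance value)
// Returns posterior summaries and retained traces of the variances.
// [[Rcpp::export(name = ".gibbs_gxe")]]
List gibbs_gxe(const arma::vec& y, List comps,
               int nIter, int burnIn, int thin,
               double priorDf, double residScale, double residFixed,
               bool traceEffects) {
  const int n = y.n_elem;
  const int nc = comps.size();

  std::vector<arma::mat> U(nc), P(nc);
  std::vector<arma::vec> d(nc), b(nc), u(nc);
  arma::vec priorScale(nc), fixedVar(nc), sig2(nc);
  int nPred = 0;

  for (int c = 0; c < nc; ++c) {
    List cc = comps[c];
    U[c] = as<arma::mat>(cc["U"]);
    d[c] = as<arma::vec>(cc["d"]);
    P[c] = as<arma::mat>(cc["P"]);
    priorScale[c] = as<double>(cc["priorScale"]);
    fixedVar[c] = as<double>(cc["fixed"]);
    b[c] = arma::zeros(d[c].n_elem);
    u[c] = arma::zeros(n);
    sig2[c] = R_IsNA(fixedVar[c])
      ? priorScale[c] * priorDf / (priorDf + 2.0)   // prior mode
      : fixedVar[c];
    nPred = P[c].n_rows;  // identical across components
  }

  double mu = arma::mean(y);
  double sig2e = R_IsNA(residFixed)
    ? residScale * priorDf / (priorDf + 2.0)
    : residFixed;

  arma::vec e = y - mu;  // running residual y - mu - sum(u)

  const int nRet = (nIter - burnIn) / thin;
  arma::mat varTrace(nRet, nc + 2);  // sig2 comps, sig2e, mu
  arma::vec fittedSum(n, arma::fill::zeros), fittedSq(n, arma::fill::zeros);
  arma::vec predSum(nPred, arma::fill::zeros), predSq(nPred, arma::fill::zeros);
  std::vector<arma::vec> uSum(nc), uSq(nc);
  std::vector<arma::mat> uTrace(nc);
  for (int c = 0; c < nc; ++c) {
    uSum[c] = arma::zeros(n);
    uSq[c] = arma::zeros(n);
    if (traceEffects) uTrace[c] = arma::mat(n, nRet);
  }

  RNGScope scope;
  int kept = 0;

  for (int it = 0; it < nIter; ++it) {
    // intercept, flat prior
    e += mu;
    mu = arma::mean(e) + R::rnorm(0.0, std::sqrt(sig2e / n));
    e -= mu;

    // random components in the eigenbasis
    for (int c = 0; c < nc; ++c) {
      e += u[c];
      arma::vec rhs = U[c].t() * e;
      const int k = d[c].n_elem;
      for (int j = 0; j < k; ++j) {
        double prec = 1.0 / (sig2[c] * d[c][j]) + 1.0 / sig2e;
        double v = 1.0 / prec;
        double m = v * rhs[j] / sig2e;
        b[c][j] = m + std::sqrt(v) * norm_rand();
      }
      u[c] = U[c] * b[c];
      e -= u[c];

      if (R_IsNA(fixedVar[c])) {
        double ss = arma::accu(arma::square(b[c]) / d[c]);
        double df = priorDf + k;
        sig2[c] = (priorDf * priorScale[c] + ss) / R::rchisq(df);
      }
    }

    // residual variance
    if (R_IsNA(residFixed)) {
      double ss = arma::dot(e, e);
      sig2e = (priorDf * residScale + ss) / R::rchisq(priorDf + n);
    }

    if (it >= burnIn && (it - burnIn) % thin == 0) {
      if (kept < nRet) {
        for (int c = 0; c < nc; ++c) varTrace(kept, c) = sig2[c];
        varTrace(kept, nc) = sig2e;
        varTrace(kept, nc + 1) = mu;

        arma::vec fit(n, arma::fill::zeros);
        for (int c = 0; c < nc; ++c) fit += u[c];
        fit += mu;
        fittedSum += fit;
        fittedSq += arma::square(fit);

        if (nPred > 0) {
          arma::vec pr(nPred, arma::fill::zeros);
          for (int c = 0; c < nc; ++c) pr += P[c] * b[c];
          pr += mu;
          predSum += pr;
          predSq += arma::square(pr);
        }
        for (int c = 0; c < nc; ++c) {
          uSum[c] += u[c];
          uSq[c] += arma::square(u[c]);
          if (traceEffects) uTrace[c].col(kept) = u[c];
        }
        ++kept;
      }
    }
  }

  List effMean(nc), effTr(nc);
  for (int c = 0; c < nc; ++c) {
    effMean[c] = wrap(uSum[c] / kept);
    if (traceEffects) effTr[c] = wrap(uTrace[c]);
  }

  return List::create(
    _["varTrace"] = varTrace,
    _["fittedMean"] = fittedSum / kept,
    _["fittedSd"] = arma::sqrt(arma::clamp(
        fittedSq / kept - arma::square(fittedSum / kept), 0.0,
        arma::datum::inf)),
    _["predMean"] = predSum / std::max(kept, 1),
    _["predSd"] = arma::sqrt(arma::clamp(
        predSq / std::max(kept, 1) - arma::square(predSum / std::max(kept, 1)),
        0.0, arma::datum::inf)),
    _["effects"] = effMean,
    _["effectTraces"] = effTr,
    _["nRetained"] = kept);
}
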