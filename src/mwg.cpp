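// Metropolis-within-Gibbs sampler for the binomial mixed logit model.
//
// Componentwise random-walk Metropolis on the fixed effects and the
// per-animal random effects, and a Metropolis step on log(sigma_alpha)
// targeting its full conditional in hierarchical mode. The linear
// predictor is maintained incrementally: each column of X touches only
// its nonzero rows (interaction columns under treatment coding are
// sparse), so a proposal costs O(#nonzero rows) rather than O(n).
// Proposal scales adapt toward the target acceptance rate during
// burn-in only, then freeze, preserving the stationary distribution.
// Uses R's RNG so set.seed() in R governs determinism.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// log Bernoulli-logit likelihood contribution of one observation,
// stable for |eta| up to about 700
static inline double llrow(double eta, double y) {
  double lse = eta > 0 ? eta + std::log1p(std::exp(-eta))
                       : std::log1p(std::exp(eta));
  return y * eta - lse;
}

// [[Rcpp::export]]
List mwg_sample_cpp(NumericMatrix X, IntegerVector seal, NumericVector y,
                    NumericVector priorMean, NumericVector priorSD,
                    int nSeals, bool hierarchical,
                    double sigmaAlphaInit, double hyperSD,
                    int nIter, int nBurn, int thin,
                    bool adapt, double targetAccept) {
  const int n = X.nrow(), p = X.ncol();

  // nonzero row indices per fixed-effect column
  std::vector< std::vector<int> > colIdx(p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i)
      if (X(i, j) != 0.0) colIdx[j].push_back(i);

  // rows per seal
  std::vector< std::vector<int> > sealIdx(nSeals);
  for (int i = 0; i < n; ++i) sealIdx[seal[i]].push_back(i);

  std::vector<double> beta(p, 0.0), alpha(nSeals, 0.0), eta(n, 0.0);
  double sigma = sigmaAlphaInit > 0 ? sigmaAlphaInit : 1.0;

  // cached per-row log-likelihood terms and a proposal scratch buffer
  std::vector<double> llcur(n), llprop(n);
  for (int i = 0; i < n; ++i) llcur[i] = llrow(0.0, y[i]);

  const int nPar = p + nSeals + 1;
  std::vector<double> prop(nPar, 0.2);
  prop[p + nSeals] = 0.3;  // log-sigma scale
  std::vector<int> accBurn(nPar, 0), accKeep(nPar, 0);
  int adaptInterval = 50, sinceAdapt = 0;

  int nKeepIter = nIter - nBurn;
  int nOut = nKeepIter / thin;
  NumericMatrix draws(nOut, nPar);
  int outRow = 0, keptIter = 0;

  for (int it = 0; it < nIter; ++it) {
    bool burn = it < nBurn;

    // fixed effects
    for (int j = 0; j < p; ++j) {
      double d = R::rnorm(0.0, prop[j]);
      double bNew = beta[j] + d;
      double dll = 0.0;
      const std::vector<int>& rows = colIdx[j];
      for (size_t r = 0; r < rows.size(); ++r) {
        int i = rows[r];
        double lp = llrow(eta[i] + X(i, j) * d, y[i]);
        llprop[i] = lp;
        dll += lp - llcur[i];
      }
      double dPrior =
        (-0.5 * std::pow((bNew - priorMean[j]) / priorSD[j], 2)) -
        (-0.5 * std::pow((beta[j] - priorMean[j]) / priorSD[j], 2));
      if (std::log(R::runif(0.0, 1.0)) < dll + dPrior) {
        beta[j] = bNew;
        for (size_t r = 0; r < rows.size(); ++r) {
          int i = rows[r];
          eta[i] += X(i, j) * d;
          llcur[i] = llprop[i];
        }
        if (burn) ++accBurn[j]; else ++accKeep[j];
      }
    }

    // random effects
    for (int s = 0; s < nSeals; ++s) {
      double d = R::rnorm(0.0, prop[p + s]);
      double aNew = alpha[s] + d;
      double dll = 0.0;
      const std::vector<int>& rows = sealIdx[s];
      for (size_t r = 0; r < rows.size(); ++r) {
        int i = rows[r];
        double lp = llrow(eta[i] + d, y[i]);
        llprop[i] = lp;
        dll += lp - llcur[i];
      }
      double dPrior = (-0.5 * aNew * aNew / (sigma * sigma)) -
                      (-0.5 * alpha[s] * alpha[s] / (sigma * sigma));
      if (std::log(R::runif(0.0, 1.0)) < dll + dPrior) {
        alpha[s] = aNew;
        for (size_t r = 0; r < rows.size(); ++r) {
          int i = rows[r];
          eta[i] += d;
          llcur[i] = llprop[i];
        }
        if (burn) ++accBurn[p + s]; else ++accKeep[p + s];
      }
    }

    // sigma_alpha: Metropolis on the log scale against its full
    // conditional (Normal likelihood of alpha, half-Normal prior,
    // plus the log-scale Jacobian)
    if (hierarchical) {
      int js = p + nSeals;
      double ls = std::log(sigma);
      double lsNew = ls + R::rnorm(0.0, prop[js]);
      double sNew = std::exp(lsNew);
      double ssq = 0.0;
      for (int s = 0; s < nSeals; ++s) ssq += alpha[s] * alpha[s];
      double lpOld = -nSeals * ls - 0.5 * ssq / (sigma * sigma)
                     - 0.5 * sigma * sigma / (hyperSD * hyperSD) + ls;
      double lpNew = -nSeals * lsNew - 0.5 * ssq / (sNew * sNew)
                     - 0.5 * sNew * sNew / (hyperSD * hyperSD) + lsNew;
      if (std::log(R::runif(0.0, 1.0)) < lpNew - lpOld) {
        sigma = sNew;
        if (burn) ++accBurn[js]; else ++accKeep[js];
      }
    }

    // proposal adaptation, burn-in only
    if (adapt && burn) {
      if (++sinceAdapt == adaptInterval) {
        for (int k = 0; k < nPar; ++k) {
          double rate = (double)accBurn[k] / adaptInterval;
          double f = std::exp(rate - targetAccept);
          if (f < 0.5) f = 0.5;
          if (f > 2.0) f = 2.0;
          prop[k] *= f;
          if (prop[k] < 1e-4) prop[k] = 1e-4;
          if (prop[k] > 10.0) prop[k] = 10.0;
          accBurn[k] = 0;
        }
        sinceAdapt = 0;
      }
    }

    if (!burn) {
      ++keptIter;
      if (keptIter % thin == 0 && outRow < nOut) {
        for (int j = 0; j < p; ++j) draws(outRow, j) = beta[j];
        for (int s = 0; s < nSeals; ++s) draws(outRow, p + s) = alpha[s];
        draws(outRow, p + nSeals) = sigma;
        ++outRow;
      }
    }
  }

  NumericVector acc(nPar);
  for (int k = 0; k < nPar; ++k)
    acc[k] = nKeepIter > 0 ? (double)accKeep[k] / nKeepIter : NA_REAL;
  if (!hierarchical) acc[p + nSeals] = 0.0;

  return List::create(_["draws"] = draws,
                      _["acceptance"] = acc,
                      _["proposalSD"] = NumericVector(prop.begin(),
                                                      prop.end()));
}
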