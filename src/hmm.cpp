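#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scaled forward-backward for a 2-state HMM.  logem is n x 2 with the
// per-bin emission log-densities; rows for missing bins must be 0 (the
// emission term is omitted so transitions still propagate through gaps).
// Returns the data log-likelihood, the posterior state probabilities
// (gamma) and the summed transition posteriors (xi_sum).
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix logem, NumericMatrix trans,
                          NumericVector init) {
  const int n = logem.nrow();
  NumericMatrix alpha(n, 2), beta(n, 2), gamma(n, 2);
  NumericVector scale(n);
  NumericMatrix em(n, 2);
  for (int t = 0; t < n; ++t)
    for (int s = 0; s < 2; ++s) em(t, s) = std::exp(logem(t, s));

  alpha(0, 0) = init[0] * em(0, 0);
  alpha(0, 1) = init[1] * em(0, 1);
  scale[0] = alpha(0, 0) + alpha(0, 1);
  alpha(0, 0) /= scale[0];
  alpha(0, 1) /= scale[0];
  for (int t = 1; t < n; ++t) {
    for (int s = 0; s < 2; ++s) {
      alpha(t, s) = (alpha(t - 1, 0) * trans(0, s) +
                     alpha(t - 1, 1) * trans(1, s)) * em(t, s);
    }
    scale[t] = alpha(t, 0) + alpha(t, 1);
    alpha(t, 0) /= scale[t];
    alpha(t, 1) /= scale[t];
  }

  beta(n - 1, 0) = 1.0;
  beta(n - 1, 1) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    for (int s = 0; s < 2; ++s) {
      beta(t, s) = (trans(s, 0) * em(t + 1, 0) * beta(t + 1, 0) +
                    trans(s, 1) * em(t + 1, 1) * beta(t + 1, 1)) / scale[t + 1];
    }
  }

  double loglik = 0.0;
  for (int t = 0; t < n; ++t) loglik += std::log(scale[t]);

  for (int t = 0; t < n; ++t) {
    double g0 = alpha(t, 0) * beta(t, 0);
    double g1 = alpha(t, 1) * beta(t, 1);
    double tot = g0 + g1;
    gamma(t, 0) = g0 / tot;
    gamma(t, 1) = g1 / tot;
  }

  NumericMatrix xi_sum(2, 2);
  for (int t = 0; t < n - 1; ++t) {
    double denom = 0.0;
    double x[2][2];
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j) {
        x[i][j] = alpha(t, i) * trans(i, j) * em(t + 1, j) * beta(t + 1, j);
        denom += x[i][j];
      }
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j) xi_sum(i, j) += x[i][j] / denom;
  }

  return List::create(Named("loglik") = loglik, Named("gamma") = gamma,
                      Named("xi_sum") = xi_sum);
}

// Most-probable state path (joint MAP decoding) for a 2-state HMM.
// Returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericMatrix logem, NumericMatrix trans,
                          NumericVector init) {
  const int n = logem.nrow();
  NumericMatrix delta(n, 2);
  IntegerMatrix psi(n, 2);
  double lt[2][2];
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j) lt[i][j] = std::log(trans(i, j));

  delta(0, 0) = std::log(init[0]) + logem(0, 0);
  delta(0, 1) = std::log(init[1]) + logem(0, 1);
  for (int t = 1; t < n; ++t) {
    for (int j = 0; j < 2; ++j) {
      double c0 = delta(t - 1, 0) + lt[0][j];
      double c1 = delta(t - 1, 1) + lt[1][j];
      if (c0 >= c1) {
        delta(t, j) = c0 + logem(t, j);
        psi(t, j) = 0;
      } else {
        delta(t, j) = c1 + logem(t, j);
        psi(t, j) = 1;
      }
    }
  }
  IntegerVector path(n);
  int s = delta(n - 1, 0) >= delta(n - 1, 1) ? 0 : 1;
  path[n - 1] = s + 1;
  for (int t = n - 2; t >= 0; --t) {
    s = psi(t + 1, s);
    path[t] = s + 1;
  }
  return path;
}
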