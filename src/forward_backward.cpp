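#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward recursion for one observation sequence.
// logB: T x K emission log-densities; A: K x K row-stochastic transitions;
// eta: initial distribution. Per-row max is subtracted before exponentiating
// and per-position scaling constants keep the recursion in range for
// arbitrarily long sequences; the log-likelihood is recovered from the
// scaling constants.
// [[Rcpp::export(name = ".fb_scaled")]]
List fb_scaled(NumericMatrix logB, NumericMatrix A, NumericVector eta) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix b(T, K), alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector cvec(T), m(T);
  double loglik = 0.0;

  for (int t = 0; t < T; ++t) {
    double mx = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > mx) mx = logB(t, k);
    m[t] = mx;
    for (int k = 0; k < K; ++k) b(t, k) = std::exp(logB(t, k) - mx);
  }

  // forward
  double c0 = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = eta[k] * b(0, k); c0 += alpha(0, k); }
  if (c0 <= 0.0) stop("forward recursion underflow at t = 1");
  for (int k = 0; k < K; ++k) alpha(0, k) /= c0;
  cvec[0] = c0;
  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int i = 0; i < K; ++i) s += alpha(t - 1, i) * A(i, j);
      alpha(t, j) = s * b(t, j);
      ct += alpha(t, j);
    }
    if (ct <= 0.0) stop("forward recursion underflow at t = %d", t + 1);
    for (int j = 0; j < K; ++j) alpha(t, j) /= ct;
    cvec[t] = ct;
  }
  for (int t = 0; t < T; ++t) loglik += std::log(cvec[t]) + m[t];

  // backward (scaled by the forward constants)
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += A(i, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, i) = s / cvec[t + 1];
    }
  }

  // posteriors and summed pairwise expectations
  NumericMatrix xi_sum(K, K);
  for (int t = 0; t < T; ++t) {
    double norm = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); norm += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= norm;
  }
  for (int t = 0; t < T - 1; ++t) {
    double norm = 0.0;
    std::vector<double> xi(K * K);
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j) {
        double v = alpha(t, i) * A(i, j) * b(t + 1, j) * beta(t + 1, j);
        xi[i * K + j] = v;
        norm += v;
      }
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j) xi_sum(i, j) += xi[i * K + j] / norm;
  }

  return List::create(_["posterior"] = gamma, _["xi_sum"] = xi_sum,
                      _["loglik"] = loglik);
}
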