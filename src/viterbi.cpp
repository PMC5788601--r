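#include <Rcpp.h>
using namespace Rcpp;

// Viterbi path of a homogeneous Gaussian-emission HMM with shared
// emission sd, uniform initial distribution, self-transition
// probability 1 - p*(K-1) and cross-transition p. Returns 1-based
// state indices. Emission constants shared across states cancel.
// [[Rcpp::export(name = ".viterbi_gauss")]]
IntegerVector viterbi_gauss(NumericVector x, NumericVector means,
                            double sd, double breakpoint_prior) {
  const int n = x.size(), K = means.size();
  const double log_self = std::log(1.0 - breakpoint_prior * (K - 1));
  const double log_cross = std::log(breakpoint_prior);
  NumericMatrix delta(K, n);
  IntegerMatrix psi(K, n);
  const double inv2s2 = 1.0 / (2.0 * sd * sd);

  for (int k = 0; k < K; ++k) {
    double d = x[0] - means[k];
    delta(k, 0) = -d * d * inv2s2;
    psi(k, 0) = 0;
  }
  for (int t = 1; t < n; ++t) {
    // best predecessor overall and per-state
    for (int k = 0; k < K; ++k) {
      double best = delta(0, t - 1) + (k == 0 ? log_self : log_cross);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = delta(j, t - 1) + (j == k ? log_self : log_cross);
        if (v > best) { best = v; arg = j; }
      }
      double d = x[t] - means[k];
      delta(k, t) = best - d * d * inv2s2;
      psi(k, t) = arg;
    }
  }
  IntegerVector path(n);
  int best = 0;
  for (int k = 1; k < K; ++k)
    if (delta(k, n - 1) > delta(best, n - 1)) best = k;
  path[n - 1] = best;
  for (int t = n - 1; t > 0; --t) {
    best = psi(best, t);
    path[t - 1] = best;
  }
  return path + 1;
}
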