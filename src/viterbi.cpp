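#include <Rcpp.h>
using namespace Rcpp;

// Viterbi decoding for a K-state homogeneous HMM with Gaussian emissions.
// Transition: log_stay on the diagonal, log_switch elsewhere. Ties in the
// backtrace (and in the terminal state choice) are broken toward
// `prefer_state` (0-based), then toward the lower state index.

// [[Rcpp::export]]
IntegerVector viterbi_gaussian_cpp(NumericVector x, NumericVector means,
                                   double sd, double log_stay,
                                   double log_switch, int prefer_state) {
  int n = x.size(), K = means.size();
  if (n == 0) return IntegerVector(0);

  // state evaluation order implementing the tie-break
  std::vector<int> order(K);
  order[0] = prefer_state;
  int k = 1;
  for (int s = 0; s < K; ++s) if (s != prefer_state) order[k++] = s;

  NumericMatrix delta(n, K);
  IntegerMatrix psi(n, K);
  double log_init = -std::log((double)K);
  double c = -std::log(sd) - 0.5 * std::log(2.0 * M_PI);
  double inv2v = 1.0 / (2.0 * sd * sd);

  for (int s = 0; s < K; ++s) {
    double d = x[0] - means[s];
    delta(0, s) = log_init + c - d * d * inv2v;
    psi(0, s) = -1;
  }
  for (int t = 1; t < n; ++t) {
    for (int s = 0; s < K; ++s) {
      double bestv = -INFINITY; int bestp = prefer_state;
      for (int oi = 0; oi < K; ++oi) {
        int p = order[oi];
        double v = delta(t - 1, p) + (p == s ? log_stay : log_switch);
        if (v > bestv) { bestv = v; bestp = p; }
      }
      double d = x[t] - means[s];
      delta(t, s) = bestv + c - d * d * inv2v;
      psi(t, s) = bestp;
    }
  }
  double bestv = -INFINITY; int bests = prefer_state;
  for (int oi = 0; oi < K; ++oi) {
    int s = order[oi];
    if (delta(n - 1, s) > bestv) { bestv = delta(n - 1, s); bests = s; }
  }
  IntegerVector path(n);
  path[n - 1] = bests;
  for (int t = n - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path;
}
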