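#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Residual sum of squares of a straight-line (intercept + slope) fit to
// x[i..j] (1-based, inclusive) against the sample index. Prefix sums give
// O(1) evaluation; the centered index moment n(n^2-1)/12 is closed-form,
// so no catastrophic cancellation for long segments.
static inline double seg_rss(const std::vector<double>& P1,
                             const std::vector<double>& P2,
                             const std::vector<double>& Pk,
                             int i, int j) {
  const double n = j - i + 1;
  if (n < 2) return 0.0;
  const double sy  = P1[j] - P1[i - 1];
  const double syy = P2[j] - P2[i - 1];
  const double sky = Pk[j] - Pk[i - 1];
  const double sxx = n * (n * n - 1.0) / 12.0;
  const double sxy = sky - 0.5 * (i + j) * sy;
  double rss = (syy - sy * sy / n) - sxy * sxy / sxx;
  return rss > 0.0 ? rss : 0.0;
}

// PELT (pruned exact linear time) minimisation of
//   sum_segments RSS_linear(segment) + beta * (#segments - 1)
// with a minimum segment length. Returns interior segment ends (1-based
// sample indices); the RSS cost is superadditive under concatenation, so
// pruning with K = 0 keeps the search exact.
// [[Rcpp::export]]
IntegerVector pelt_linear(NumericVector x, double beta, int minseg) {
  const int N = x.size();
  if (minseg < 2) minseg = 2;
  if (N < 2 * minseg) return IntegerVector(0);

  std::vector<double> P1(N + 1, 0.0), P2(N + 1, 0.0), Pk(N + 1, 0.0);
  for (int k = 1; k <= N; ++k) {
    P1[k] = P1[k - 1] + x[k - 1];
    P2[k] = P2[k - 1] + x[k - 1] * x[k - 1];
    Pk[k] = Pk[k - 1] + (double)k * x[k - 1];
  }

  const double INF = R_PosInf;
  std::vector<double> F(N + 1, INF);
  std::vector<int> prev(N + 1, 0);
  F[0] = -beta;
  // With a minimum segment length, a candidate dominated at step t may
  // still be optimal for targets T < t + minseg (the dominating split at
  // t is not yet legal there), so removal is delayed by minseg steps.
  std::vector<int> cand, expiry;
  cand.push_back(0);
  expiry.push_back(0);  // 0 = no pending removal

  for (int t = minseg; t <= N; ++t) {
    {
      std::vector<int> kc, ke;
      kc.reserve(cand.size());
      ke.reserve(cand.size());
      for (size_t c = 0; c < cand.size(); ++c)
        if (expiry[c] == 0 || t < expiry[c]) {
          kc.push_back(cand[c]);
          ke.push_back(expiry[c]);
        }
      cand.swap(kc);
      expiry.swap(ke);
    }
    double best = INF;
    int arg = 0;
    std::vector<double> val(cand.size(), INF);
    for (size_t c = 0; c < cand.size(); ++c) {
      const int tau = cand[c];
      if (t - tau < minseg) continue;
      const double v = F[tau] + seg_rss(P1, P2, Pk, tau + 1, t) + beta;
      val[c] = v;
      if (v < best) { best = v; arg = tau; }
    }
    F[t] = best;
    prev[t] = arg;
    for (size_t c = 0; c < cand.size(); ++c)
      if (expiry[c] == 0 && val[c] != INF && val[c] - beta > best)
        expiry[c] = t + minseg;
    cand.push_back(t);
    expiry.push_back(0);
  }

  std::vector<int> cps;
  for (int t = prev[N]; t > 0; t = prev[t]) cps.push_back(t);
  IntegerVector out(cps.size());
  for (size_t i = 0; i < cps.size(); ++i) out[i] = cps[cps.size() - 1 - i];
  return out;
}
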