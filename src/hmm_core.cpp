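#include <Rcpp.h>
using namespace Rcpp;

// log(sum(exp(x))) over a small fixed-size buffer
static inline double logsumexp2(const double *x, int k) {
  double m = x[0];
  for (int i = 1; i < k; ++i) if (x[i] > m) m = x[i];
  if (!R_finite(m)) return m;
  double s = 0.0;
  for (int i = 0; i < k; ++i) s += std::exp(x[i] - m);
  return m + std::log(s);
}

// Forward-backward on one uninterrupted observation segment.
// logemit: T x K matrix of per-state log emission densities.
// Returns posterior state probabilities (gamma), expected transition
// counts, the posterior of the first observation (for pi updates) and the
// segment log-likelihood. All in natural log space.
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix logemit, NumericMatrix logA,
                          NumericVector logpi) {
  const int T = logemit.nrow(), K = logemit.ncol();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
  NumericMatrix trans(K, K);
  std::vector<double> buf(K);

  for (int k = 0; k < K; ++k) alpha(0, k) = logpi[k] + logemit(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j) buf[j] = alpha(t - 1, j) + logA(j, k);
      alpha(t, k) = logsumexp2(buf.data(), K) + logemit(t, k);
    }
  for (int k = 0; k < K; ++k) buf[k] = alpha(T - 1, k);
  const double loglik = logsumexp2(buf.data(), K);

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 0.0;
  for (int t = T - 2; t >= 0; --t)
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j)
        buf[j] = logA(k, j) + logemit(t + 1, j) + beta(t + 1, j);
      beta(t, k) = logsumexp2(buf.data(), K);
    }

  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      gamma(t, k) = std::exp(alpha(t, k) + beta(t, k) - loglik);

  for (int t = 0; t < T - 1; ++t)
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        trans(j, k) += std::exp(alpha(t, j) + logA(j, k) +
                                logemit(t + 1, k) + beta(t + 1, k) - loglik);

  NumericVector g1(K);
  for (int k = 0; k < K; ++k) g1[k] = gamma(0, k);
  return List::create(_["gamma"] = gamma, _["trans"] = trans,
                      _["gamma1"] = g1, _["loglik"] = loglik);
}

// Viterbi decoding; ties broken toward the lower state index so that, with
// state 1 = background, ambiguous bins are called background.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericMatrix logemit, NumericMatrix logA,
                          NumericVector logpi) {
  const int T = logemit.nrow(), K = logemit.ncol();
  if (T == 0) return IntegerVector(0);
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);

  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logemit(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      int best = 0;
      double bestv = delta(t - 1, 0) + logA(0, k);
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + logA(j, k);
        if (v > bestv) { bestv = v; best = j; }  // strict: ties keep lower j
      }
      delta(t, k) = bestv + logemit(t, k);
      psi(t, k) = best;
    }

  IntegerVector path(T);
  int best = 0;
  double bestv = delta(T - 1, 0);
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > bestv) { bestv = delta(T - 1, k); best = k; }
  path[T - 1] = best + 1;
  for (int t = T - 2; t >= 0; --t) {
    best = psi(t + 1, best);
    path[t] = best + 1;
  }
  return path;
}
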