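#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// log-sum-exp of a length-K buffer
static inline double lse(const std::vector<double>& v) {
  double m = v[0];
  for (size_t i = 1; i < v.size(); ++i) if (v[i] > m) m = v[i];
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// Negative log-likelihood and gradient of a linear-chain CRF over a set of
// sentences. Each sentence is a List with:
//   feats: IntegerVector of 0-based feature ids, all tokens concatenated
//   ptr:   IntegerVector length T+1, token t uses feats[ptr[t]..ptr[t+1])
//   y:     IntegerVector length T of 0-based gold label ids
// W: d x K emission weights, trans: K x K, start: K.
// [[Rcpp::export]]
List crf_nll_grad(List sentences, NumericMatrix W, NumericMatrix trans,
                  NumericVector start) {
  const int d = W.nrow(), K = W.ncol();
  NumericMatrix gW(d, K), gT(K, K);
  NumericVector gS(K);
  double nll = 0.0;

  for (int s = 0; s < sentences.size(); ++s) {
    List sent = sentences[s];
    IntegerVector feats = sent["feats"];
    IntegerVector ptr = sent["ptr"];
    IntegerVector y = sent["y"];
    const int T = y.size();
    if (T == 0) continue;

    // node potentials
    NumericMatrix node(T, K);
    for (int t = 0; t < T; ++t)
      for (int f = ptr[t]; f < ptr[t + 1]; ++f)
        for (int k = 0; k < K; ++k) node(t, k) += W(feats[f], k);

    // forward
    NumericMatrix alpha(T, K);
    std::vector<double> buf(K);
    for (int k = 0; k < K; ++k) alpha(0, k) = start[k] + node(0, k);
    for (int t = 1; t < T; ++t)
      for (int k = 0; k < K; ++k) {
        for (int j = 0; j < K; ++j) buf[j] = alpha(t - 1, j) + trans(j, k);
        alpha(t, k) = lse(buf) + node(t, k);
      }
    for (int k = 0; k < K; ++k) buf[k] = alpha(T - 1, k);
    const double logZ = lse(buf);

    // backward
    NumericMatrix beta(T, K);
    for (int t = T - 2; t >= 0; --t)
      for (int j = 0; j < K; ++j) {
        for (int k = 0; k < K; ++k)
          buf[k] = trans(j, k) + node(t + 1, k) + beta(t + 1, k);
        beta(t, j) = lse(buf);
      }

    // gold path score
    double gold = start[y[0]] + node(0, y[0]);
    for (int t = 1; t < T; ++t)
      gold += trans(y[t - 1], y[t]) + node(t, y[t]);
    nll += logZ - gold;

    // expected minus empirical counts
    for (int t = 0; t < T; ++t) {
      for (int k = 0; k < K; ++k) {
        double m = std::exp(alpha(t, k) + beta(t, k) - logZ);
        double delta = m - (y[t] == k ? 1.0 : 0.0);
        if (t == 0) gS[k] += delta;
        for (int f = ptr[t]; f < ptr[t + 1]; ++f)
          gW(feats[f], k) += delta;
      }
      if (t > 0) {
        for (int j = 0; j < K; ++j)
          for (int k = 0; k < K; ++k) {
            double p = std::exp(alpha(t - 1, j) + trans(j, k) + node(t, k) +
                                beta(t, k) - logZ);
            gT(j, k) += p;
          }
        gT(y[t - 1], y[t]) -= 1.0;
      }
    }
  }
  return List::create(Named("nll") = nll, Named("gW") = gW,
                      Named("gT") = gT, Named("gS") = gS);
}

// Viterbi over explicit potentials: node (T x K), trans (K x K), start (K).
// Ties resolve to the lowest state index (states are kept lexicographically
// sorted on the R side). Returns 1-based label indices and the path score.
// [[Rcpp::export]]
List chain_viterbi(NumericMatrix node, NumericMatrix trans,
                   NumericVector start) {
  const int T = node.nrow(), K = node.ncol();
  if (T == 0)
    return List::create(Named("path") = IntegerVector(0),
                        Named("score") = R_NegInf);
  NumericMatrix delta(T, K);
  IntegerMatrix back(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = start[k] + node(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + trans(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + node(t, k);
      back(t, k) = arg;
    }
  double best = R_NegInf; int arg = 0;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  IntegerVector path(T);
  path[T - 1] = arg;
  for (int t = T - 1; t > 0; --t) path[t - 1] = back(t, path[t]);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return List::create(Named("path") = path, Named("score") = best);
}
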