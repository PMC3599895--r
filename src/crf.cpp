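// Linear-chain CRF internals: penalised negative log-likelihood with
// analytic gradient (forward-backward) and Viterbi decoding.
//
// A "line" is List(feats = List of IntegerVector (1-based feature ids,
// possibly empty), labels = IntegerVector (1-based label ids)).
// Parameter vector layout: init[L] | trans[L*L, from-major] | emit[F*L,
// feature-major]; all scores are sums of active-feature weights.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double logsumexp(const double* v, int n) {
  double m = v[0];
  for (int i = 1; i < n; ++i) if (v[i] > m) m = v[i];
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// emission scores for one line: T x L (column-major in a flat vector)
static void emission_scores(const List& feats, const double* emit, int L,
                            std::vector<double>& s) {
  int T = feats.size();
  s.assign((size_t)T * L, 0.0);
  for (int t = 0; t < T; ++t) {
    IntegerVector f = feats[t];
    const int* fp = INTEGER(f);
    for (int j = 0; j < f.size(); ++j) {
      const double* w = emit + (size_t)(fp[j] - 1) * L;
      for (int l = 0; l < L; ++l) s[(size_t)t * L + l] += w[l];
    }
  }
}

// [[Rcpp::export]]
List crf_nll_grad(List lines, NumericVector par, double lambda, int n_feat,
                  int n_lab) {
  const int L = n_lab;
  const double* p_init = REAL(par);
  const double* p_trans = p_init + L;
  const double* p_emit = p_trans + (size_t)L * L;
  if ((size_t)par.size() != (size_t)L + (size_t)L * L + (size_t)n_feat * L)
    stop("parameter vector has wrong length");

  NumericVector grad(par.size(), 0.0);
  double* g_init = REAL(grad);
  double* g_trans = g_init + L;
  double* g_emit = g_trans + (size_t)L * L;
  double nll = 0.0;

  std::vector<double> s, alpha, beta, tmp(L);
  for (int li = 0; li < lines.size(); ++li) {
    List line = lines[li];
    List feats = line["feats"];
    IntegerVector labels = line["labels"];
    int T = feats.size();
    if (T == 0) continue;
    emission_scores(feats, p_emit, L, s);

    alpha.assign((size_t)T * L, 0.0);
    beta.assign((size_t)T * L, 0.0);
    for (int l = 0; l < L; ++l) alpha[l] = p_init[l] + s[l];
    for (int t = 1; t < T; ++t)
      for (int l = 0; l < L; ++l) {
        for (int k = 0; k < L; ++k)
          tmp[k] = alpha[(size_t)(t - 1) * L + k] + p_trans[k * L + l];
        alpha[(size_t)t * L + l] = logsumexp(tmp.data(), L) + s[(size_t)t * L + l];
      }
    double logZ = logsumexp(&alpha[(size_t)(T - 1) * L], L);
    for (int t = T - 2; t >= 0; --t)
      for (int k = 0; k < L; ++k) {
        for (int l = 0; l < L; ++l)
          tmp[l] = p_trans[k * L + l] + s[(size_t)(t + 1) * L + l] +
                   beta[(size_t)(t + 1) * L + l];
        beta[(size_t)t * L + k] = logsumexp(tmp.data(), L);
      }

    // gold score and empirical counts
    double gold = p_init[labels[0] - 1] + s[labels[0] - 1];
    g_init[labels[0] - 1] -= 1.0;
    for (int t = 1; t < T; ++t) {
      gold += p_trans[(labels[t - 1] - 1) * L + (labels[t] - 1)] +
              s[(size_t)t * L + (labels[t] - 1)];
      g_trans[(labels[t - 1] - 1) * L + (labels[t] - 1)] -= 1.0;
    }
    for (int t = 0; t < T; ++t) {
      IntegerVector f = feats[t];
      const int* fp = INTEGER(f);
      for (int j = 0; j < f.size(); ++j)
        g_emit[(size_t)(fp[j] - 1) * L + (labels[t] - 1)] -= 1.0;
    }
    nll += logZ - gold;

    // expected counts
    std::vector<double> marg(L);
    for (int t = 0; t < T; ++t) {
      for (int l = 0; l < L; ++l)
        marg[l] = std::exp(alpha[(size_t)t * L + l] + beta[(size_t)t * L + l] -
                           logZ);
      if (t == 0)
        for (int l = 0; l < L; ++l) g_init[l] += marg[l];
      IntegerVector f = feats[t];
      const int* fp = INTEGER(f);
      for (int j = 0; j < f.size(); ++j) {
        double* g = g_emit + (size_t)(fp[j] - 1) * L;
        for (int l = 0; l < L; ++l) g[l] += marg[l];
      }
      if (t > 0)
        for (int k = 0; k < L; ++k) {
          double a = alpha[(size_t)(t - 1) * L + k];
          for (int l = 0; l < L; ++l)
            g_trans[k * L + l] +=
                std::exp(a + p_trans[k * L + l] + s[(size_t)t * L + l] +
                         beta[(size_t)t * L + l] - logZ);
        }
    }
  }

  // L2 penalty
  double pen = 0.0;
  for (R_xlen_t i = 0; i < par.size(); ++i) {
    pen += par[i] * par[i];
    grad[i] += lambda * par[i];
  }
  nll += 0.5 * lambda * pen;
  return List::create(_["nll"] = nll, _["grad"] = grad);
}

// [[Rcpp::export]]
List crf_viterbi(List lines, NumericVector par, int n_feat, int n_lab) {
  const int L = n_lab;
  const double* p_init = REAL(par);
  const double* p_trans = p_init + L;
  const double* p_emit = p_trans + (size_t)L * L;
  if ((size_t)par.size() != (size_t)L + (size_t)L * L + (size_t)n_feat * L)
    stop("parameter vector has wrong length");

  List out(lines.size());
  std::vector<double> s, delta;
  std::vector<int> back;
  for (int li = 0; li < lines.size(); ++li) {
    List line = lines[li];
    List feats = line["feats"];
    int T = feats.size();
    if (T == 0) { out[li] = IntegerVector(0); continue; }
    emission_scores(feats, p_emit, L, s);
    delta.assign((size_t)T * L, 0.0);
    back.assign((size_t)T * L, 0);
    for (int l = 0; l < L; ++l) delta[l] = p_init[l] + s[l];
    for (int t = 1; t < T; ++t)
      for (int l = 0; l < L; ++l) {
        int arg = 0;
        double best = delta[(size_t)(t - 1) * L] + p_trans[l];
        for (int k = 1; k < L; ++k) {
          double v = delta[(size_t)(t - 1) * L + k] + p_trans[k * L + l];
          if (v > best) { best = v; arg = k; }
        }
        delta[(size_t)t * L + l] = best + s[(size_t)t * L + l];
        back[(size_t)t * L + l] = arg;
      }
    IntegerVector path(T);
    int arg = 0;
    for (int l = 1; l < L; ++l)
      if (delta[(size_t)(T - 1) * L + l] > delta[(size_t)(T - 1) * L + arg])
        arg = l;
    path[T - 1] = arg + 1;
    for (int t = T - 1; t > 0; --t) {
      arg = back[(size_t)t * L + arg];
      path[t - 1] = arg + 1;
    }
    out[li] = path;
  }
  return out;
}
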