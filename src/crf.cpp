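// Linear-chain CRF core: penalized negative log-likelihood with gradient
// (forward-backward with per-position scaling) and Viterbi decoding.
//
// Parameter vector layout, for F features and L labels:
//   [0, F*L)          emission weights, w[f*L + y]
//   [F*L, F*L + L*L)  transition weights, T[y_prev*L + y]
//   next L            start weights
//   next L            end weights
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline void node_scores(const std::vector<std::vector<int> > &x,
                               const double *wem, const double *wstart,
                               const double *wend, int L,
                               std::vector<double> &s) {
  int n = x.size();
  s.assign((size_t)n * L, 0.0);
  for (int t = 0; t < n; ++t) {
    double *st = &s[(size_t)t * L];
    for (size_t k = 0; k < x[t].size(); ++k) {
      const double *row = wem + (size_t)x[t][k] * L;
      for (int y = 0; y < L; ++y) st[y] += row[y];
    }
    if (t == 0)
      for (int y = 0; y < L; ++y) st[y] += wstart[y];
    if (t == n - 1)
      for (int y = 0; y < L; ++y) st[y] += wend[y];
  }
}

static void to_cpp_sentence(SEXP feats, std::vector<std::vector<int> > &x) {
  List fl(feats);
  int n = fl.size();
  x.resize(n);
  for (int t = 0; t < n; ++t) {
    IntegerVector v(fl[t]);
    x[t].assign(v.begin(), v.end());
  }
}

// [[Rcpp::export(name = ".crf_nll_grad")]]
List crf_nll_grad(NumericVector w, List feats, List labels, int L, int F,
                  double c2) {
  const double *wem = w.begin();
  const double *wtr = wem + (size_t)F * L;
  const double *wstart = wtr + (size_t)L * L;
  const double *wend = wstart + L;
  NumericVector grad((size_t)F * L + (size_t)L * L + 2 * L);
  double *gem = grad.begin();
  double *gtr = gem + (size_t)F * L;
  double *gstart = gtr + (size_t)L * L;
  double *gend = gstart + L;
  double nll = 0.0;
  int S = feats.size();
  std::vector<double> s, alpha, beta, scale, mu;
  std::vector<std::vector<int> > x;
  std::vector<double> etr((size_t)L * L);
  for (int si = 0; si < S; ++si) {
    to_cpp_sentence(feats[si], x);
    IntegerVector y(labels[si]);
    int n = x.size();
    if (n == 0) continue;
    node_scores(x, wem, wstart, wend, L, s);
    // exponentiated, per-position max-shifted node potentials
    std::vector<double> psi((size_t)n * L);
    std::vector<double> shift(n);
    for (int t = 0; t < n; ++t) {
      double m = s[(size_t)t * L];
      for (int yy = 1; yy < L; ++yy) m = std::max(m, s[(size_t)t * L + yy]);
      shift[t] = m;
      for (int yy = 0; yy < L; ++yy)
        psi[(size_t)t * L + yy] = std::exp(s[(size_t)t * L + yy] - m);
    }
    std::vector<double> etrans((size_t)L * L);
    for (int a = 0; a < L; ++a)
      for (int b = 0; b < L; ++b)
        etrans[(size_t)a * L + b] = std::exp(wtr[(size_t)a * L + b]);
    alpha.assign((size_t)n * L, 0.0);
    beta.assign((size_t)n * L, 0.0);
    scale.assign(n, 0.0);
    // forward with scaling
    double logZ = 0.0;
    for (int yy = 0; yy < L; ++yy) alpha[yy] = psi[yy];
    double c = 0.0;
    for (int yy = 0; yy < L; ++yy) c += alpha[yy];
    for (int yy = 0; yy < L; ++yy) alpha[yy] /= c;
    scale[0] = c;
    logZ += std::log(c) + shift[0];
    for (int t = 1; t < n; ++t) {
      double *at = &alpha[(size_t)t * L];
      const double *ap = &alpha[(size_t)(t - 1) * L];
      for (int b = 0; b < L; ++b) {
        double acc = 0.0;
        for (int a = 0; a < L; ++a) acc += ap[a] * etrans[(size_t)a * L + b];
        at[b] = acc * psi[(size_t)t * L + b];
      }
      c = 0.0;
      for (int b = 0; b < L; ++b) c += at[b];
      for (int b = 0; b < L; ++b) at[b] /= c;
      scale[t] = c;
      logZ += std::log(c) + shift[t];
    }
    // backward, scaled with the forward scales
    for (int yy = 0; yy < L; ++yy)
      beta[(size_t)(n - 1) * L + yy] = 1.0 / scale[n - 1];
    for (int t = n - 2; t >= 0; --t) {
      double *bt = &beta[(size_t)t * L];
      const double *bn = &beta[(size_t)(t + 1) * L];
      for (int a = 0; a < L; ++a) {
        double acc = 0.0;
        for (int b = 0; b < L; ++b)
          acc += etrans[(size_t)a * L + b] * psi[(size_t)(t + 1) * L + b] *
                 bn[b];
        bt[a] = acc / scale[t];
      }
    }
    // unary marginals mu[t][y] = alpha[t][y] * beta[t][y] * scale[t]
    mu.assign((size_t)n * L, 0.0);
    for (int t = 0; t < n; ++t) {
      double tot = 0.0;
      for (int yy = 0; yy < L; ++yy) {
        mu[(size_t)t * L + yy] = alpha[(size_t)t * L + yy] *
                                 beta[(size_t)t * L + yy] * scale[t];
        tot += mu[(size_t)t * L + yy];
      }
      for (int yy = 0; yy < L; ++yy) mu[(size_t)t * L + yy] /= tot;
    }
    // gold score
    double gold = 0.0;
    for (int t = 0; t < n; ++t) {
      gold += s[(size_t)t * L + y[t]];
      if (t > 0) gold += wtr[(size_t)y[t - 1] * L + y[t]];
    }
    nll += logZ - gold;
    // emission gradient: model expectation - empirical
    for (int t = 0; t < n; ++t) {
      for (size_t k = 0; k < x[t].size(); ++k) {
        double *g = gem + (size_t)x[t][k] * L;
        for (int yy = 0; yy < L; ++yy) g[yy] += mu[(size_t)t * L + yy];
        g[y[t]] -= 1.0;
      }
    }
    for (int yy = 0; yy < L; ++yy) {
      gstart[yy] += mu[yy];
      gend[yy] += mu[(size_t)(n - 1) * L + yy];
    }
    gstart[y[0]] -= 1.0;
    gend[y[n - 1]] -= 1.0;
    // pairwise marginals for the transition gradient
    for (int t = 1; t < n; ++t) {
      const double *ap = &alpha[(size_t)(t - 1) * L];
      const double *bt = &beta[(size_t)t * L];
      double tot = 0.0;
      for (int a = 0; a < L; ++a)
        for (int b = 0; b < L; ++b) {
          double v = ap[a] * etrans[(size_t)a * L + b] *
                     psi[(size_t)t * L + b] * bt[b];
          etr[(size_t)a * L + b] = v;
          tot += v;
        }
      for (int a = 0; a < L; ++a)
        for (int b = 0; b < L; ++b)
          gtr[(size_t)a * L + b] += etr[(size_t)a * L + b] / tot;
      gtr[(size_t)y[t - 1] * L + y[t]] -= 1.0;
    }
  }
  // L2 penalty 0.5 * c2 * ||w||^2
  size_t P = w.size();
  double pen = 0.0;
  for (size_t i = 0; i < P; ++i) {
    pen += w[i] * w[i];
    grad[i] += c2 * w[i];
  }
  nll += 0.5 * c2 * pen;
  return List::create(Named("nll") = nll, Named("grad") = grad);
}

// [[Rcpp::export(name = ".crf_viterbi")]]
IntegerVector crf_viterbi(NumericVector w, List feats, int L, int F) {
  const double *wem = w.begin();
  const double *wtr = wem + (size_t)F * L;
  const double *wstart = wtr + (size_t)L * L;
  const double *wend = wstart + L;
  std::vector<std::vector<int> > x;
  to_cpp_sentence(feats, x);
  int n = x.size();
  IntegerVector out(n);
  if (n == 0) return out;
  std::vector<double> s;
  node_scores(x, wem, wstart, wend, L, s);
  std::vector<double> delta(s.begin(), s.begin() + L);
  std::vector<int> back((size_t)n * L, 0);
  std::vector<double> nd(L);
  for (int t = 1; t < n; ++t) {
    for (int b = 0; b < L; ++b) {
      double best = delta[0] + wtr[b];
      int arg = 0;
      for (int a = 1; a < L; ++a) {
        double v = delta[a] + wtr[(size_t)a * L + b];
        if (v > best) { best = v; arg = a; }
      }
      nd[b] = best + s[(size_t)t * L + b];
      back[(size_t)t * L + b] = arg;
    }
    delta = nd;
  }
  int arg = 0;
  for (int yy = 1; yy < L; ++yy) if (delta[yy] > delta[arg]) arg = yy;
  out[n - 1] = arg;
  for (int t = n - 1; t > 0; --t) {
    arg = back[(size_t)t * L + arg];
    out[t - 1] = arg;
  }
  return out;
}
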