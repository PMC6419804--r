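// Linear-chain CRF inner loops: emission scoring, log-space
// forward/backward, Viterbi, and the gradient of the log-likelihood.
//
// Conventions shared with the R wrappers:
//  * an instance is a pair (feats, offs): `feats` holds 0-based feature
//    ids for all positions concatenated, `offs` has length n+1 and
//    offs[j]..offs[j+1]-1 index the features active at position j;
//  * W is the (n_features x L) emission weight matrix, Tr the
//    ((L+1) x L) transition matrix whose last row is the virtual START
//    state providing the j = 1 transition;
//  * ties in Viterbi are broken toward the lowest label index (strict
//    "greater than" comparisons keep the earliest candidate).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double lse(const std::vector<double>& v) {
  double m = v[0];
  for (double x : v) if (x > m) m = x;
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (double x : v) s += std::exp(x - m);
  return m + std::log(s);
}

// emission score matrix, n x L
static std::vector<double> emissions(const IntegerVector& feats,
                                     const IntegerVector& offs,
                                     const NumericMatrix& W, int L) {
  int n = offs.size() - 1;
  std::vector<double> E((size_t)n * L, 0.0);
  for (int j = 0; j < n; ++j) {
    for (int k = offs[j]; k < offs[j + 1]; ++k) {
      int f = feats[k];
      for (int y = 0; y < L; ++y) E[(size_t)j * L + y] += W(f, y);
    }
  }
  return E;
}

static void forward(const std::vector<double>& E, const NumericMatrix& Tr,
                    int n, int L, std::vector<double>& alpha) {
  std::vector<double> tmp(L);
  for (int y = 0; y < L; ++y) alpha[y] = Tr(L, y) + E[y];
  for (int j = 1; j < n; ++j) {
    for (int y = 0; y < L; ++y) {
      for (int yp = 0; yp < L; ++yp)
        tmp[yp] = alpha[(size_t)(j - 1) * L + yp] + Tr(yp, y);
      alpha[(size_t)j * L + y] = lse(tmp) + E[(size_t)j * L + y];
    }
  }
}

// [[Rcpp::export]]
double cpp_crf_logZ(IntegerVector feats, IntegerVector offs,
                    NumericMatrix W, NumericMatrix Tr) {
  int L = Tr.ncol();
  int n = offs.size() - 1;
  std::vector<double> E = emissions(feats, offs, W, L);
  std::vector<double> alpha((size_t)n * L);
  forward(E, Tr, n, L, alpha);
  std::vector<double> last(alpha.end() - L, alpha.end());
  return lse(last);
}

// [[Rcpp::export]]
double cpp_crf_score(IntegerVector feats, IntegerVector offs,
                     IntegerVector labels, NumericMatrix W,
                     NumericMatrix Tr) {
  int L = Tr.ncol();
  int n = offs.size() - 1;
  double s = 0.0;
  for (int j = 0; j < n; ++j) {
    int y = labels[j];
    for (int k = offs[j]; k < offs[j + 1]; ++k) s += W(feats[k], y);
    s += (j == 0) ? Tr(L, y) : Tr(labels[j - 1], y);
  }
  return s;
}

// [[Rcpp::export]]
IntegerVector cpp_crf_viterbi(IntegerVector feats, IntegerVector offs,
                              NumericMatrix W, NumericMatrix Tr) {
  int L = Tr.ncol();
  int n = offs.size() - 1;
  std::vector<double> E = emissions(feats, offs, W, L);
  std::vector<double> delta((size_t)n * L);
  std::vector<int> back((size_t)n * L, -1);
  for (int y = 0; y < L; ++y) delta[y] = Tr(L, y) + E[y];
  for (int j = 1; j < n; ++j) {
    for (int y = 0; y < L; ++y) {
      double best = delta[(size_t)(j - 1) * L] + Tr(0, y);
      int arg = 0;
      for (int yp = 1; yp < L; ++yp) {
        double cand = delta[(size_t)(j - 1) * L + yp] + Tr(yp, y);
        if (cand > best) { best = cand; arg = yp; }  // ties keep lowest yp
      }
      delta[(size_t)j * L + y] = best + E[(size_t)j * L + y];
      back[(size_t)j * L + y] = arg;
    }
  }
  int ylast = 0;
  double best = delta[(size_t)(n - 1) * L];
  for (int y = 1; y < L; ++y) {
    if (delta[(size_t)(n - 1) * L + y] > best) {
      best = delta[(size_t)(n - 1) * L + y];
      ylast = y;
    }
  }
  IntegerVector path(n);
  path[n - 1] = ylast;
  for (int j = n - 1; j > 0; --j) path[j - 1] = back[(size_t)j * L + path[j]];
  return path;
}

// Total log-likelihood of the gold labelings and its gradient with
// respect to W and Tr (observed minus expected feature counts).
// [[Rcpp::export]]
List cpp_crf_loglik_grad(List feats_list, List offs_list, List gold_list,
                         NumericMatrix W, NumericMatrix Tr,
                         bool want_grad = true) {
  int L = Tr.ncol();
  int nF = W.nrow();
  double ll = 0.0;
  NumericMatrix gW(want_grad ? nF : 1, want_grad ? L : 1);
  NumericMatrix gT(want_grad ? L + 1 : 1, want_grad ? L : 1);
  int n_inst = feats_list.size();
  std::vector<double> tmp(L);

  for (int i = 0; i < n_inst; ++i) {
    IntegerVector feats = feats_list[i];
    IntegerVector offs = offs_list[i];
    IntegerVector gold = gold_list[i];
    int n = offs.size() - 1;
    std::vector<double> E = emissions(feats, offs, W, L);
    std::vector<double> alpha((size_t)n * L), beta((size_t)n * L, 0.0);
    forward(E, Tr, n, L, alpha);
    for (int j = n - 2; j >= 0; --j) {
      for (int yp = 0; yp < L; ++yp) {
        for (int y = 0; y < L; ++y)
          tmp[y] = Tr(yp, y) + E[(size_t)(j + 1) * L + y] +
                   beta[(size_t)(j + 1) * L + y];
        beta[(size_t)j * L + yp] = lse(tmp);
      }
    }
    std::vector<double> last(alpha.end() - L, alpha.end());
    double logZ = lse(last);

    // gold score
    double gs = 0.0;
    for (int j = 0; j < n; ++j) {
      int y = gold[j];
      gs += E[(size_t)j * L + y];
      gs += (j == 0) ? Tr(L, y) : Tr(gold[j - 1], y);
    }
    ll += gs - logZ;
    if (!want_grad) continue;

    // observed counts
    for (int j = 0; j < n; ++j) {
      int y = gold[j];
      for (int k = offs[j]; k < offs[j + 1]; ++k) gW(feats[k], y) += 1.0;
      if (j == 0) gT(L, y) += 1.0; else gT(gold[j - 1], y) += 1.0;
    }
    // expected emission counts via node marginals
    for (int j = 0; j < n; ++j) {
      for (int y = 0; y < L; ++y) {
        double p = std::exp(alpha[(size_t)j * L + y] +
                            beta[(size_t)j * L + y] - logZ);
        if (p == 0.0) continue;
        for (int k = offs[j]; k < offs[j + 1]; ++k) gW(feats[k], y) -= p;
        if (j == 0) gT(L, y) -= p;
      }
    }
    // expected transition counts via edge marginals
    for (int j = 1; j < n; ++j) {
      for (int yp = 0; yp < L; ++yp) {
        double a = alpha[(size_t)(j - 1) * L + yp];
        for (int y = 0; y < L; ++y) {
          double p = std::exp(a + Tr(yp, y) + E[(size_t)j * L + y] +
                              beta[(size_t)j * L + y] - logZ);
          gT(yp, y) -= p;
        }
      }
    }
  }
  if (want_grad) {
    return List::create(_["loglik"] = ll, _["gW"] = gW, _["gT"] = gT);
  }
  return List::create(_["loglik"] = ll);
}
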