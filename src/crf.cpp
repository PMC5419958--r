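// Second-order linear-chain CRF over labels {B=0, I=1, O=2} with a
// begin-of-sentence context label (BOS=3).  State features are
// (feature, current label) weights in W (nfeat x 3, column-major);
// transition features are label trigrams (a, b, c) with a, b in {B,I,O,BOS}
// and c in {B,I,O}, stored flat as Tr[a*12 + b*3 + c] (length 48).
//
// Dynamic programming runs over pair states (prev, cur): 4 x 3 = 12 states.
// Single-token sentences use state scores only (no transition context).

#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const int NL = 3;    // emitting labels
static const int BOS = 3;   // context-only label
static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline int tri(int a, int b, int c) { return a * 12 + b * 3 + c; }

static inline double lse(const double *v, int n) {
  double m = NEG_INF;
  for (int i = 0; i < n; ++i) if (v[i] > m) m = v[i];
  if (m == NEG_INF) return NEG_INF;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// state scores: n x 3 (row-major in a vector)
static void state_scores(const List &feats, const NumericMatrix &W,
                         std::vector<double> &S) {
  int n = feats.size();
  S.assign((size_t)n * NL, 0.0);
  for (int i = 0; i < n; ++i) {
    IntegerVector fi = feats[i];
    for (int k = 0; k < fi.size(); ++k) {
      int f = fi[k] - 1;  // R is 1-based
      if (f < 0 || f >= W.nrow()) continue;
      for (int c = 0; c < NL; ++c) S[(size_t)i * NL + c] += W(f, c);
    }
  }
}

// forward pass; alpha is n x 12 (pair = prev*3 + cur); returns logZ
static double forward_pass(int n, const std::vector<double> &S,
                           const NumericVector &Tr,
                           std::vector<double> &alpha) {
  alpha.assign((size_t)n * 12, NEG_INF);
  for (int c = 0; c < NL; ++c)
    alpha[(size_t)0 * 12 + BOS * 3 + c] = S[c] + Tr[tri(BOS, BOS, c)];
  for (int i = 1; i < n; ++i) {
    for (int b = 0; b < NL; ++b) {
      for (int c = 0; c < NL; ++c) {
        double acc[4];
        for (int a = 0; a < 4; ++a) {
          double prev = alpha[(size_t)(i - 1) * 12 + a * 3 + b];
          acc[a] = (prev == NEG_INF) ? NEG_INF : prev + Tr[tri(a, b, c)];
        }
        double v = lse(acc, 4);
        alpha[(size_t)i * 12 + b * 3 + c] =
            (v == NEG_INF) ? NEG_INF : v + S[(size_t)i * NL + c];
      }
    }
  }
  return lse(&alpha[(size_t)(n - 1) * 12], 12);
}

static void backward_pass(int n, const std::vector<double> &S,
                          const NumericVector &Tr,
                          std::vector<double> &beta) {
  beta.assign((size_t)n * 12, NEG_INF);
  for (int p = 0; p < 12; ++p) beta[(size_t)(n - 1) * 12 + p] = 0.0;
  for (int i = n - 2; i >= 0; --i) {
    for (int a = 0; a < 4; ++a) {
      for (int b = 0; b < NL; ++b) {
        double acc[3];
        for (int c = 0; c < NL; ++c) {
          acc[c] = Tr[tri(a, b, c)] + S[(size_t)(i + 1) * NL + c] +
                   beta[(size_t)(i + 1) * 12 + b * 3 + c];
        }
        beta[(size_t)i * 12 + a * 3 + b] = lse(acc, 3);
      }
    }
  }
}

// [[Rcpp::export(name = ".crf_corpus_nll_grad")]]
List crf_corpus_nll_grad(List feats_corpus, List labels_corpus,
                         NumericMatrix W, NumericVector Tr) {
  int nfeat = W.nrow();
  NumericMatrix gradW(nfeat, NL);
  NumericVector gradTr(48);
  double nll = 0.0;
  int ns = feats_corpus.size();
  std::vector<double> S, alpha, beta;

  for (int s = 0; s < ns; ++s) {
    List feats = feats_corpus[s];
    IntegerVector y = labels_corpus[s];
    int n = feats.size();
    if (n == 0) continue;
    state_scores(feats, W, S);

    if (n == 1) {
      double sc[3] = {S[0], S[1], S[2]};
      double logZ = lse(sc, 3);
      int y0 = y[0] - 1;
      nll += logZ - S[y0];
      IntegerVector fi = feats[0];
      for (int c = 0; c < NL; ++c) {
        double p = std::exp(S[c] - logZ) - (c == y0 ? 1.0 : 0.0);
        for (int k = 0; k < fi.size(); ++k) {
          int f = fi[k] - 1;
          if (f >= 0 && f < nfeat) gradW(f, c) += p;
        }
      }
      continue;
    }

    double logZ = forward_pass(n, S, Tr, alpha);
    backward_pass(n, S, Tr, beta);

    // gold score and empirical counts
    double gold = 0.0;
    for (int i = 0; i < n; ++i) gold += S[(size_t)i * NL + (y[i] - 1)];
    gold += Tr[tri(BOS, BOS, y[0] - 1)];
    gradTr[tri(BOS, BOS, y[0] - 1)] -= 1.0;
    for (int i = 1; i < n; ++i) {
      int a = (i >= 2) ? (y[i - 2] - 1) : BOS;
      gold += Tr[tri(a, y[i - 1] - 1, y[i] - 1)];
      gradTr[tri(a, y[i - 1] - 1, y[i] - 1)] -= 1.0;
    }
    nll += logZ - gold;

    // expected state counts via pair marginals
    for (int i = 0; i < n; ++i) {
      double pc[3] = {0.0, 0.0, 0.0};
      for (int a = 0; a < 4; ++a) {
        for (int c = 0; c < NL; ++c) {
          double la = alpha[(size_t)i * 12 + a * 3 + c];
          if (la == NEG_INF) continue;
          double lb = beta[(size_t)i * 12 + a * 3 + c];
          pc[c] += std::exp(la + lb - logZ);
        }
      }
      IntegerVector fi = feats[i];
      for (int c = 0; c < NL; ++c) {
        double g = pc[c] - (c == (y[i] - 1) ? 1.0 : 0.0);
        for (int k = 0; k < fi.size(); ++k) {
          int f = fi[k] - 1;
          if (f >= 0 && f < nfeat) gradW(f, c) += g;
        }
      }
      if (i == 0) {
        for (int c = 0; c < NL; ++c)
          gradTr[tri(BOS, BOS, c)] += pc[c];
      }
    }
    // expected trigram counts on transitions i -> i+1
    for (int i = 0; i + 1 < n; ++i) {
      for (int a = 0; a < 4; ++a) {
        for (int b = 0; b < NL; ++b) {
          double la = alpha[(size_t)i * 12 + a * 3 + b];
          if (la == NEG_INF) continue;
          for (int c = 0; c < NL; ++c) {
            double q = la + Tr[tri(a, b, c)] +
                       S[(size_t)(i + 1) * NL + c] +
                       beta[(size_t)(i + 1) * 12 + b * 3 + c] - logZ;
            gradTr[tri(a, b, c)] += std::exp(q);
          }
        }
      }
    }
  }
  return List::create(Named("nll") = nll,
                      Named("gradW") = gradW,
                      Named("gradTr") = gradTr);
}

// [[Rcpp::export(name = ".crf_logZ")]]
double crf_logZ(List feats, NumericMatrix W, NumericVector Tr) {
  int n = feats.size();
  if (n == 0) return 0.0;
  std::vector<double> S, alpha;
  state_scores(feats, W, S);
  if (n == 1) {
    double sc[3] = {S[0], S[1], S[2]};
    return lse(sc, 3);
  }
  return forward_pass(n, S, Tr, alpha);
}

// Viterbi decode; ties broken toward the smaller label index (B < I < O)
// and, among previous-pair candidates, the smaller previous label.
// [[Rcpp::export(name = ".crf_viterbi")]]
IntegerVector crf_viterbi(List feats, NumericMatrix W, NumericVector Tr) {
  int n = feats.size();
  if (n == 0) return IntegerVector(0);
  std::vector<double> S;
  state_scores(feats, W, S);

  if (n == 1) {
    int best = 0;
    for (int c = 1; c < NL; ++c) if (S[c] > S[best]) best = c;
    return IntegerVector::create(best + 1);
  }

  std::vector<double> delta((size_t)n * 12, NEG_INF);
  std::vector<int> back((size_t)n * 12, -1);
  for (int c = 0; c < NL; ++c)
    delta[(size_t)0 * 12 + BOS * 3 + c] = S[c] + Tr[tri(BOS, BOS, c)];
  for (int i = 1; i < n; ++i) {
    for (int b = 0; b < NL; ++b) {
      for (int c = 0; c < NL; ++c) {
        double best = NEG_INF;
        int arg = -1;
        for (int a = 0; a < 4; ++a) {
          double prev = delta[(size_t)(i - 1) * 12 + a * 3 + b];
          if (prev == NEG_INF) continue;
          double v = prev + Tr[tri(a, b, c)];
          if (v > best) { best = v; arg = a; }
        }
        if (arg >= 0) {
          delta[(size_t)i * 12 + b * 3 + c] = best + S[(size_t)i * NL + c];
          back[(size_t)i * 12 + b * 3 + c] = arg;
        }
      }
    }
  }
  // terminal: first-maximum over (b, c) scanned in label order
  double best = NEG_INF;
  int bb = -1, bc = -1;
  for (int b = 0; b < NL; ++b) {
    for (int c = 0; c < NL; ++c) {
      double v = delta[(size_t)(n - 1) * 12 + b * 3 + c];
      if (v > best) { best = v; bb = b; bc = c; }
    }
  }
  IntegerVector out(n);
  int curB = bb, curC = bc;
  out[n - 1] = curC + 1;
  for (int i = n - 1; i >= 1; --i) {
    int a = back[(size_t)i * 12 + curB * 3 + curC];
    out[i - 1] = curB + 1;
    curC = curB;
    curB = a;
  }
  return out;
}
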