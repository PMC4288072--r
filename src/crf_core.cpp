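// Linear-chain CRF inference core.
//
// Forward-backward uses the scaled (normal-space) recursions: transition
// potentials are exponentiated once per call and each position's forward
// vector is renormalised, so the per-position inner loop is pure
// multiply-add. Masked (-Inf) transitions become exact zeros. Viterbi is
// max-sum in log space (no exp needed).

#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// scaled forward-backward over rows [t0, t1) of U; writes node marginals
// into `node` (same rows), accumulates expected transition counts into
// `trans_exp`, first/last-position marginals into begF/begL. Returns logZ.
static double fb_block(const NumericMatrix& U, int t0, int t1,
                       const std::vector<double>& expT,
                       const NumericVector& begin, const NumericVector& endw,
                       NumericMatrix& node, std::vector<double>& trans_exp) {
  const int L = U.ncol(), T = t1 - t0;
  std::vector<double> eu(T * L);         // exp(U - rowmax), row-scaled
  std::vector<double> umax(T);
  for (int t = 0; t < T; ++t) {
    double m = NEG_INF;
    for (int y = 0; y < L; ++y) m = std::max(m, U(t0 + t, y));
    if (m == NEG_INF) m = 0.0;
    umax[t] = m;
    for (int y = 0; y < L; ++y) {
      double u = U(t0 + t, y);
      eu[t * L + y] = (u == NEG_INF) ? 0.0 : std::exp(u - m);
    }
  }
  std::vector<double> a(T * L), b(T * L), scale(T);
  double logZ = 0.0;
  // forward
  for (int y = 0; y < L; ++y) {
    double bg = begin[y];
    a[y] = (bg == NEG_INF) ? 0.0 : std::exp(bg) * eu[y];
  }
  for (int t = 0; t < T; ++t) {
    if (t > 0)
      for (int y = 0; y < L; ++y) {
        double s = 0.0;
        for (int yp = 0; yp < L; ++yp)
          s += a[(t - 1) * L + yp] * expT[yp * L + y];
        a[t * L + y] = s * eu[t * L + y];
      }
    double s = 0.0;
    for (int y = 0; y < L; ++y) s += a[t * L + y];
    if (s <= 0.0) return NEG_INF;        // every path masked
    for (int y = 0; y < L; ++y) a[t * L + y] /= s;
    scale[t] = s;
    logZ += std::log(s) + umax[t];
  }
  double zend = 0.0;
  std::vector<double> ew(L);
  for (int y = 0; y < L; ++y) {
    ew[y] = (endw[y] == NEG_INF) ? 0.0 : std::exp(endw[y]);
    zend += a[(T - 1) * L + y] * ew[y];
  }
  if (zend <= 0.0) return NEG_INF;
  logZ += std::log(zend);
  // backward (scaled by the forward scales, so a.b products are posteriors)
  for (int y = 0; y < L; ++y) b[(T - 1) * L + y] = ew[y] / zend;
  for (int t = T - 2; t >= 0; --t) {
    for (int y = 0; y < L; ++y) {
      double s = 0.0;
      for (int yn = 0; yn < L; ++yn)
        s += expT[y * L + yn] * eu[(t + 1) * L + yn] * b[(t + 1) * L + yn];
      b[t * L + y] = s / scale[t + 1];
    }
  }
  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int y = 0; y < L; ++y) {
      double p = a[t * L + y] * b[t * L + y];
      node(t0 + t, y) = p;
      s += p;
    }
    // products are already normalised up to rounding; renormalise exactly
    if (s > 0) for (int y = 0; y < L; ++y) node(t0 + t, y) /= s;
  }
  for (int t = 1; t < T; ++t) {
    double s = 0.0;
    std::vector<double> m(L * L);
    for (int yp = 0; yp < L; ++yp) {
      double ap = a[(t - 1) * L + yp];
      if (ap == 0.0) continue;
      for (int y = 0; y < L; ++y) {
        double v = ap * expT[yp * L + y] * eu[t * L + y] * b[t * L + y];
        m[yp * L + y] = v;
        s += v;
      }
    }
    if (s > 0)
      for (int i = 0; i < L * L; ++i) trans_exp[i] += m[i] / s;
  }
  return logZ;
}

static std::vector<double> exp_trans(const NumericMatrix& trans) {
  const int L = trans.nrow();
  std::vector<double> expT(L * L);
  for (int yp = 0; yp < L; ++yp)
    for (int y = 0; y < L; ++y) {
      double v = trans(yp, y);
      expT[yp * L + y] = (v == NEG_INF) ? 0.0 : std::exp(v);
    }
  return expT;
}

// [[Rcpp::export(name = ".crf_forward_backward")]]
List crf_forward_backward(NumericMatrix unary, NumericMatrix trans,
                          NumericVector begin, NumericVector endw) {
  const int T = unary.nrow(), L = unary.ncol();
  NumericMatrix node(T, L);
  std::vector<double> te(L * L, 0.0);
  double logZ = fb_block(unary, 0, T, exp_trans(trans), begin, endw, node, te);
  NumericMatrix trans_exp(L, L);
  for (int yp = 0; yp < L; ++yp)
    for (int y = 0; y < L; ++y) trans_exp(yp, y) = te[yp * L + y];
  return List::create(_["logZ"] = logZ, _["node"] = node,
                      _["trans_exp"] = trans_exp);
}

// batched version over a stacked unary matrix; `lens` gives the length of
// each sequence, in row order. Returns summed logZ, all node marginals,
// pooled expected transition counts and pooled first/last marginals.
// [[Rcpp::export(name = ".crf_fb_batch")]]
List crf_fb_batch(NumericMatrix unary, NumericMatrix trans,
                  NumericVector begin, NumericVector endw,
                  IntegerVector lens) {
  const int L = unary.ncol();
  NumericMatrix node(unary.nrow(), L);
  std::vector<double> te(L * L, 0.0);
  std::vector<double> expT = exp_trans(trans);
  NumericVector firstm(L), lastm(L);
  double logZ = 0.0;
  int t0 = 0;
  for (int s = 0; s < lens.size(); ++s) {
    int t1 = t0 + lens[s];
    double z = fb_block(unary, t0, t1, expT, begin, endw, node, te);
    if (!std::isfinite(z))
      stop("non-finite log partition in sequence %d", s + 1);
    logZ += z;
    for (int y = 0; y < L; ++y) {
      firstm[y] += node(t0, y);
      lastm[y] += node(t1 - 1, y);
    }
    t0 = t1;
  }
  NumericMatrix trans_exp(L, L);
  for (int yp = 0; yp < L; ++yp)
    for (int y = 0; y < L; ++y) trans_exp(yp, y) = te[yp * L + y];
  return List::create(_["logZ"] = logZ, _["node"] = node,
                      _["trans_exp"] = trans_exp,
                      _["first"] = firstm, _["last"] = lastm);
}

// [[Rcpp::export(name = ".crf_viterbi")]]
List crf_viterbi(NumericMatrix unary, NumericMatrix trans,
                 NumericVector begin, NumericVector endw) {
  int T = unary.nrow(), L = unary.ncol();
  NumericMatrix delta(T, L);
  IntegerMatrix back(T, L);
  for (int y = 0; y < L; ++y) { delta(0, y) = begin[y] + unary(0, y); back(0, y) = -1; }
  for (int t = 1; t < T; ++t)
    for (int y = 0; y < L; ++y) {
      double best = NEG_INF; int arg = 0;
      for (int yp = 0; yp < L; ++yp) {
        double s = delta(t - 1, yp) + trans(yp, y);
        if (s > best) { best = s; arg = yp; }   // strict >: lowest index wins ties
      }
      delta(t, y) = best + unary(t, y);
      back(t, y) = arg;
    }
  double best = NEG_INF; int arg = 0;
  for (int y = 0; y < L; ++y) {
    double s = delta(T - 1, y) + endw[y];
    if (s > best) { best = s; arg = y; }
  }
  IntegerVector path(T);
  path[T - 1] = arg;
  for (int t = T - 1; t > 0; --t) path[t - 1] = back(t, path[t]);
  return List::create(_["path"] = path, _["score"] = best);
}
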