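#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian kernel matrix on normal scores, zero diagonal (leave-one-out).
// Normalization constants are omitted: they cancel in the MI log-ratio.
// [[Rcpp::export]]
NumericMatrix cpp_kernel_matrix(NumericVector s, double h) {
  int n = s.size();
  NumericMatrix K(n, n);
  for (int j = 0; j < n; ++j) {
    K(j, j) = 0.0;
    for (int i = 0; i < j; ++i) {
      double d = (s[i] - s[j]) / h;
      double v = std::exp(-0.5 * d * d);
      K(i, j) = v;
      K(j, i) = v;
    }
  }
  return K;
}

// Plug-in MI from two normal-score vectors: average over sample points of
// log f2(x_i, y_i) - log fx(x_i) - log fy(x_i), product Gaussian kernel with
// per-axis bandwidths, leave-one-out sums. Clamped at zero.
// [[Rcpp::export]]
double cpp_mi_scores(NumericVector s, NumericVector t, double hs, double ht) {
  int n = s.size();
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double f2 = 0.0, fx = 0.0, fy = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = (s[i] - s[j]) / hs;
      double dy = (t[i] - t[j]) / ht;
      double kx = std::exp(-0.5 * dx * dx);
      double ky = std::exp(-0.5 * dy * dy);
      f2 += kx * ky;
      fx += kx;
      fy += ky;
    }
    acc += std::log(f2) - std::log(fx) - std::log(fy);
  }
  double mi = acc / n + std::log((double)(n - 1));
  return mi > 0.0 ? mi : 0.0;
}

static double mi_pair_ranks(const double *K, const double *logm, int n,
                            const int *rx, const int *ry) {
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    // symmetric K: row rx[i] read as column rx[i] (contiguous)
    const double *cx = K + (size_t)n * rx[i];
    const double *cy = K + (size_t)n * ry[i];
    double f2 = 0.0;
    for (int j = 0; j < n; ++j) f2 += cx[rx[j]] * cy[ry[j]];  // j==i: diag 0
    acc += std::log(f2) - logm[rx[i]] - logm[ry[i]];
  }
  double mi = acc / n + std::log((double)(n - 1));
  return mi > 0.0 ? mi : 0.0;
}

// Same quantity with samples pre-sorted by the x gene's rank (rx = identity):
// the x kernel column is then read sequentially, halving the gather traffic.
static double mi_pair_sorted(const double *K, const double *logm, int n,
                             const int *ry) {
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    const double *__restrict cx = K + (size_t)n * i;
    const double *__restrict cy = K + (size_t)n * ry[i];
    double f2 = 0.0;
    for (int j = 0; j < n; ++j) f2 += cx[j] * cy[ry[j]];
    acc += std::log(f2) - logm[i] - logm[ry[i]];
  }
  double mi = acc / n + std::log((double)(n - 1));
  return mi > 0.0 ? mi : 0.0;
}

// MI for one gene pair given the shared rank-kernel matrix K0 (zero diagonal)
// and logm = log(rowSums(K0)); rx, ry are 1-based untied sample ranks.
// [[Rcpp::export]]
double cpp_mi_ranks(NumericMatrix K0, NumericVector logm,
                    IntegerVector rx, IntegerVector ry) {
  int n = rx.size();
  std::vector<int> rx0(n), ry0(n);
  for (int i = 0; i < n; ++i) { rx0[i] = rx[i] - 1; ry0[i] = ry[i] - 1; }
  return mi_pair_ranks(REAL(K0), REAL(logm), n, rx0.data(), ry0.data());
}

// All-pairs MI for a rank matrix R (n samples x g genes); returns g x g
// symmetric matrix with zero diagonal.
// [[Rcpp::export]]
NumericMatrix cpp_mi_allpairs(NumericMatrix K0, NumericVector logm,
                              IntegerMatrix R) {
  int n = R.nrow(), g = R.ncol();
  std::vector<int> ranks((size_t)n * g), order((size_t)n * g);
  for (int a = 0; a < g; ++a)
    for (int i = 0; i < n; ++i) {
      int r = R(i, a) - 1;
      ranks[(size_t)a * n + i] = r;
      order[(size_t)a * n + r] = i;   // sample holding rank r of gene a
    }
  NumericMatrix M(g, g);
  const double *K = REAL(K0);
  const double *lm = REAL(logm);
  std::vector<int> ry(n);
  for (int a = 0; a < g; ++a) {
    const int *oa = order.data() + (size_t)a * n;
    for (int b = 0; b < a; ++b) {
      const int *rb = ranks.data() + (size_t)b * n;
      for (int t = 0; t < n; ++t) ry[t] = rb[oa[t]];
      double mi = mi_pair_sorted(K, lm, n, ry.data());
      M(a, b) = mi;
      M(b, a) = mi;
    }
  }
  return M;
}

// Null MI values: for each of the n_null rows of `pairs` (1-based gene
// indices into R), compute MI between gene a and gene b with b's samples
// permuted by the corresponding column of `perms` (1-based).
// [[Rcpp::export]]
NumericVector cpp_mi_null(NumericMatrix K0, NumericVector logm,
                          IntegerMatrix R, IntegerMatrix pairs,
                          IntegerMatrix perms) {
  int n = R.nrow();
  int m = pairs.nrow();
  NumericVector out(m);
  std::vector<int> ord(n), yr(n), ry(n);
  const double *K = REAL(K0);
  const double *lm = REAL(logm);
  for (int k = 0; k < m; ++k) {
    int a = pairs(k, 0) - 1, b = pairs(k, 1) - 1;
    for (int i = 0; i < n; ++i) {
      ord[R(i, a) - 1] = i;                 // sample holding rank r of gene a
      yr[i] = R(perms(i, k) - 1, b) - 1;    // permuted y ranks per sample
    }
    for (int t = 0; t < n; ++t) ry[t] = yr[ord[t]];
    out[k] = mi_pair_sorted(K, lm, n, ry.data());
  }
  return out;
}

// Data processing inequality pruning with TF protection.
// M: symmetric MI matrix, 0 = absent edge.  For every triangle (i,j,k) the
// weakest edge (i,j) is marked when MI_ij < min(MI_ik, MI_jk) * (1 - eps);
// a mark on an edge incident to a TF is void when a min-achieving alternative
// edge of that triangle joins two non-TFs.  All valid marks are applied
// simultaneously; returns the logical removal matrix.
// [[Rcpp::export]]
LogicalMatrix cpp_dpi(NumericMatrix M, double eps, LogicalVector is_tf) {
  int g = M.nrow();
  LogicalMatrix rem(g, g);
  double slack = 1.0 - eps;
  for (int i = 0; i < g; ++i) {
    for (int j = 0; j < i; ++j) {
      double mij = M(i, j);
      if (mij <= 0.0) continue;
      bool marked = false;
      for (int k = 0; k < g && !marked; ++k) {
        if (k == i || k == j) continue;
        double mik = M(i, k), mjk = M(j, k);
        if (mik <= 0.0 || mjk <= 0.0) continue;
        double mn = mik < mjk ? mik : mjk;
        if (mij >= mn * slack) continue;
        if (is_tf[i] || is_tf[j]) {
          bool exempt = false;
          if (mik == mn && !is_tf[i] && !is_tf[k]) exempt = true;
          if (mjk == mn && !is_tf[j] && !is_tf[k]) exempt = true;
          if (exempt) continue;
        }
        marked = true;
      }
      if (marked) {
        rem(i, j) = true;
        rem(j, i) = true;
      }
    }
  }
  return rem;
}
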