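#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exhaustive scan of the per-nutrient lag grid.
//
// The R wrapper pre-computes, for every distinct usable-row window (one per
// distinct alignment start), the centred cross-product matrix of all
// 5*(L+1) lagged predictor columns, the centred predictor-response products
// and the centred response sum of squares.  Each lag combination then only
// needs a 5x5 normal-equations solve assembled from those cross-products,
// which is what makes the 4,084,101-combination full grid tractable.
//
// Column index convention: nutrient i (0..4), lag k (0..L) -> i*(L+1)+k.
// Lexicographic combination index: k1 most significant,
//   idx = (((k1*(L+1)+k2)*(L+1)+k3)*(L+1)+k4)*(L+1)+k5.
// Ties on r are broken toward the smallest index because iteration is in
// increasing idx and replacement requires a strict improvement.

static inline bool solve5(const double A_in[5][5], const double b_in[5],
                          double beta[5]) {
  double A[5][5], b[5];
  double scale = 0.0;
  for (int i = 0; i < 5; ++i) {
    for (int j = 0; j < 5; ++j) {
      A[i][j] = A_in[i][j];
      if (std::fabs(A[i][j]) > scale) scale = std::fabs(A[i][j]);
    }
    b[i] = b_in[i];
  }
  if (scale <= 0.0) return false;
  const double tol = 1e-12 * scale;
  for (int c = 0; c < 5; ++c) {
    int piv = c;
    for (int r = c + 1; r < 5; ++r)
      if (std::fabs(A[r][c]) > std::fabs(A[piv][c])) piv = r;
    if (std::fabs(A[piv][c]) <= tol) return false;  // rank deficient
    if (piv != c) {
      for (int j = c; j < 5; ++j) std::swap(A[c][j], A[piv][j]);
      std::swap(b[c], b[piv]);
    }
    for (int r = c + 1; r < 5; ++r) {
      double f = A[r][c] / A[c][c];
      if (f == 0.0) continue;
      for (int j = c; j < 5; ++j) A[r][j] -= f * A[c][j];
      b[r] -= f * b[c];
    }
  }
  for (int r = 4; r >= 0; --r) {
    double s = b[r];
    for (int j = r + 1; j < 5; ++j) s -= A[r][j] * beta[j];
    beta[r] = s / A[r][r];
  }
  return true;
}

// [[Rcpp::export]]
List scan_lag_grid_cpp(List gram, List gxy, NumericVector syy,
                       IntegerVector nrows, IntegerVector group_of_k,
                       int max_lag, int min_rows, bool keep_grid,
                       NumericVector subset) {
  const int L1 = max_lag + 1;
  const long long total = (long long)L1 * L1 * L1 * L1 * L1;
  const bool use_subset = subset.size() > 0;
  const long long n_eval = use_subset ? subset.size() : total;

  std::vector<NumericMatrix> G;
  std::vector<NumericVector> gy;
  for (int g = 0; g < gram.size(); ++g) {
    G.push_back(as<NumericMatrix>(gram[g]));
    gy.push_back(as<NumericVector>(gxy[g]));
  }

  NumericVector rgrid(keep_grid ? n_eval : 0);
  IntegerMatrix prof_n(5, L1);
  NumericMatrix prof_sum(5, L1), prof_sumsq(5, L1);
  long long n_usable = 0, n_unusable = 0;
  double best_r = -1.0;
  long long best_idx = -1;
  int k[5];

  for (long long pos = 0; pos < n_eval; ++pos) {
    long long idx = use_subset ? (long long)subset[pos] : pos;
    long long rem = idx;
    int kmax = 0;
    for (int i = 4; i >= 0; --i) {
      k[i] = (int)(rem % L1);
      rem /= L1;
      if (k[i] > kmax) kmax = k[i];
    }
    const int g = group_of_k[kmax];
    double r = NA_REAL;
    bool usable = false;
    if (g >= 0 && nrows[g] >= min_rows) {
      if (syy[g] <= 1e-300) {
        r = 0.0;               // constant response: fit defined as r = 0
        usable = true;
      } else {
        double A[5][5], b[5], beta[5];
        const NumericMatrix &Gm = G[g];
        const NumericVector &gv = gy[g];
        int col[5];
        for (int i = 0; i < 5; ++i) col[i] = i * L1 + k[i];
        for (int i = 0; i < 5; ++i) {
          b[i] = gv[col[i]];
          for (int j = 0; j < 5; ++j) A[i][j] = Gm(col[i], col[j]);
        }
        if (solve5(A, b, beta)) {
          double ess = 0.0;
          for (int i = 0; i < 5; ++i) ess += beta[i] * b[i];
          double r2 = ess / syy[g];
          if (r2 < 0.0) r2 = 0.0;
          if (r2 > 1.0) r2 = 1.0;
          r = std::sqrt(r2);
          usable = true;
        }
      }
    }
    if (usable) {
      ++n_usable;
      if (!use_subset) {
        for (int i = 0; i < 5; ++i) {
          prof_n(i, k[i]) += 1;
          prof_sum(i, k[i]) += r;
          prof_sumsq(i, k[i]) += r * r;
        }
      }
      if (r > best_r || (r == best_r && (best_idx < 0 || idx < best_idx))) {
        best_r = r;
        best_idx = idx;
      }
    } else {
      ++n_unusable;
    }
    if (keep_grid) rgrid[pos] = r;
  }

  return List::create(
    _["r"] = rgrid,
    _["best_index"] = (double)best_idx,
    _["best_r"] = best_r,
    _["n_usable"] = (double)n_usable,
    _["n_unusable"] = (double)n_unusable,
    _["prof_n"] = prof_n,
    _["prof_sum"] = prof_sum,
    _["prof_sumsq"] = prof_sumsq);
}
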