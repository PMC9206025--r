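// Hot numeric kernels for the network-fusion pipeline.
#include <Rcpp.h>
#include <algorithm>
#include <limits>
#include <vector>

using namespace Rcpp;

// One cross-diffusion update for a single view: the symmetrized,
// row-renormalized S * Pbar * S^T, with S a row-stochastic sparse kernel
// given in compressed sparse column form (sp, si, sx) and Pbar the mean
// full kernel of the other views. Uses sym(S P S^T) = S sym(P) S^T so every
// inner loop walks matrices in column-major order.
// [[Rcpp::export(name = ".fuse_step")]]
List fuse_step(IntegerVector sp, IntegerVector si, NumericVector sx,
               IntegerVector stp, IntegerVector sti, NumericVector stx,
               NumericMatrix Pbar, NumericMatrix Prev) {
  const int m = Pbar.nrow();
  const double* P = REAL(Pbar);       // mean full kernel of the other views
  const double* Pv = REAL(Prev);      // previous state of this view (delta)

  // Pb = (Pbar + Pbar^T) / 2; with a symmetric middle factor the product
  // S Pb S^T is symmetric, which also makes the symmetrization exact.
  std::vector<double> Pb((size_t)m * m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < m; ++i)
      Pb[(size_t)j * m + i] = 0.5 * (P[(size_t)j * m + i] + P[(size_t)i * m + j]);

  // F = S Pb S^T, one pass per output column j:
  //   tmp = Pb %*% S^T[, j]  (a handful of dense-column axpys)
  //   F[, j] = S %*% tmp     (CSC scatter; S's structure stays in cache)
  NumericMatrix Fm(m, m);
  double* F = REAL(Fm);
  std::vector<double> tmp(m);
  for (int j = 0; j < m; ++j) {
    std::fill(tmp.begin(), tmp.end(), 0.0);
    for (int q = stp[j]; q < stp[j + 1]; ++q) {
      const double s = stx[q];
      const double* pcol = &Pb[(size_t)sti[q] * m];
      for (int i = 0; i < m; ++i) tmp[i] += s * pcol[i];
    }
    double* fcol = &F[(size_t)j * m];
    for (int l = 0; l < m; ++l) {
      const double t = tmp[l];
      if (t == 0.0) continue;
      for (int q = sp[l]; q < sp[l + 1]; ++q) fcol[si[q]] += sx[q] * t;
    }
  }

  // mirror-average against rounding, renormalize rows to sum to 1, and track
  // the largest change versus the previous state of this view
  for (int j = 0; j < m; ++j)
    for (int i = j + 1; i < m; ++i) {
      const double v = 0.5 * (F[(size_t)j * m + i] + F[(size_t)i * m + j]);
      F[(size_t)j * m + i] = v;
      F[(size_t)i * m + j] = v;
    }
  std::vector<double> rs(m, 0.0);
  for (int j = 0; j < m; ++j) {
    const double* fcol = &F[(size_t)j * m];
    for (int i = 0; i < m; ++i) rs[i] += fcol[i];
  }
  std::vector<double> rinv(m);
  for (int i = 0; i < m; ++i) rinv[i] = rs[i] > 0 ? 1.0 / rs[i] : 1.0;
  double delta = 0.0;
  for (int j = 0; j < m; ++j) {
    double* fcol = &F[(size_t)j * m];
    const double* pvcol = &Pv[(size_t)j * m];
    for (int i = 0; i < m; ++i) {
      fcol[i] *= rinv[i];
      const double d = std::abs(fcol[i] - pvcol[i]);
      if (d > delta) delta = d;
    }
  }
  return List::create(Named("P") = Fm, Named("delta") = delta);
}

// Mean distance from each point to its k nearest neighbors (self excluded),
// given the full symmetric distance matrix.
// [[Rcpp::export(name = ".knn_mean_dist")]]
NumericVector knn_mean_dist(NumericMatrix D, const int k) {
  const int m = D.nrow();
  NumericVector out(m);
  std::vector<double> row(m);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < m; ++j) row[j] = D(i, j);
    row[i] = std::numeric_limits<double>::infinity();  // drop self
    std::nth_element(row.begin(), row.begin() + k - 1, row.end());
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += row[j];
    out[i] = s / k;
  }
  return out;
}

// Column indices (1-based) of the k largest off-diagonal entries per row,
// ties broken toward the smaller column index.
// [[Rcpp::export(name = ".row_topk")]]
IntegerMatrix row_topk(NumericMatrix W, const int k) {
  const int m = W.nrow();
  IntegerMatrix out(m, k);
  std::vector<int> idx;
  for (int i = 0; i < m; ++i) {
    idx.clear();
    for (int j = 0; j < m; ++j) if (j != i) idx.push_back(j);
    std::partial_sort(idx.begin(), idx.begin() + k, idx.end(),
                      [&](int a, int b) {
                        const double wa = W(i, a), wb = W(i, b);
                        if (wa != wb) return wa > wb;
                        return a < b;
                      });
    for (int j = 0; j < k; ++j) out(i, j) = idx[j] + 1;
  }
  return out;
}
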