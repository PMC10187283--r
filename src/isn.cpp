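// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shared moment bookkeeping for leave-one-out Pearson downdating.
// V is n x r (raw scale; Pearson is scale invariant). For sample s the
// pairwise correlations over the other n-1 samples come from full-sample
// sums, sums of squares and cross-products with row s removed.
namespace {

struct LooMoments {
  int n, r;
  std::vector<double> s1;   // column sums
  std::vector<double> S2;   // r x r cross-product matrix (row-major)
  explicit LooMoments(const NumericMatrix &V)
      : n(V.nrow()), r(V.ncol()), s1(r, 0.0), S2((size_t)r * r, 0.0) {
    for (int i = 0; i < r; ++i) {
      double a = 0.0;
      for (int s = 0; s < n; ++s) a += V(s, i);
      s1[i] = a;
    }
    for (int i = 0; i < r; ++i)
      for (int j = i; j < r; ++j) {
        double c = 0.0;
        for (int s = 0; s < n; ++s) c += V(s, i) * V(s, j);
        S2[(size_t)i * r + j] = c;
        S2[(size_t)j * r + i] = c;
      }
  }
};

// Fill one ISN row: |c_global - c_loo(s)| over pairs i<j in lexicographic
// order. `out` must have room for r(r-1)/2 doubles.
void isn_row(const NumericMatrix &V, const NumericVector &c_global,
             const LooMoments &M, int s, double *out,
             std::vector<double> &d1, std::vector<double> &dvar) {
  const int r = M.r;
  const double m = M.n - 1.0;
  for (int i = 0; i < r; ++i) {
    const double v = V(s, i);
    d1[i] = M.s1[i] - v;
    dvar[i] = M.S2[(size_t)i * r + i] - v * v - d1[i] * d1[i] / m;
    if (dvar[i] <= 0.0)
      stop("zero-variance feature %d when leaving out sample %d", i + 1, s + 1);
  }
  R_xlen_t idx = 0;
  for (int i = 0; i < r - 1; ++i) {
    const double vi = V(s, i);
    const double *S2i = &M.S2[(size_t)i * r];
    for (int j = i + 1; j < r; ++j) {
      const double cov = (S2i[j] - vi * V(s, j)) - d1[i] * d1[j] / m;
      const double c_loo = cov / std::sqrt(dvar[i] * dvar[j]);
      out[idx] = std::fabs(c_global[idx] - c_loo);
      ++idx;
    }
  }
}

} // namespace

// Leave-one-out individual-specific networks by moment downdating.
// c_global: length r(r-1)/2 vector of full-sample Pearson correlations in
// lexicographic (i<j) order. The phenotype-correlation terms of the network
// edge weights are cohort-level quantities common to the global and
// leave-one-out networks, so they cancel in the absolute difference and do
// not appear here. Total cost O(n r^2); equals naive recomputation up to
// rounding.
// [[Rcpp::export]]
NumericMatrix cpp_build_isns(NumericMatrix V, NumericVector c_global) {
  const int n = V.nrow(), r = V.ncol();
  const R_xlen_t k = (R_xlen_t)r * (r - 1) / 2;
  if (c_global.size() != k) stop("c_global has wrong length");
  LooMoments M(V);
  NumericMatrix W(n, k);
  std::vector<double> row(k), d1(r), dvar(r);
  for (int s = 0; s < n; ++s) {
    isn_row(V, c_global, M, s, row.data(), d1, dvar);
    for (R_xlen_t e = 0; e < k; ++e) W(s, e) = row[e];
  }
  return W;
}

// Pairwise Euclidean distances between ISN edge vectors without
// materializing the n x k edge matrix. Edges are processed in chunks: for a
// chunk of edge indices, the n x chunk slab of ISN values is computed (each
// edge exactly once) and the sample Gram matrix accumulated with one BLAS
// product per chunk. Memory O(n * chunk_edges + n^2).
// [[Rcpp::export]]
NumericMatrix cpp_isn_distances(NumericMatrix V, NumericVector c_global,
                                R_xlen_t chunk_edges) {
  const int n = V.nrow(), r = V.ncol();
  const R_xlen_t k = (R_xlen_t)r * (r - 1) / 2;
  if (c_global.size() != k) stop("c_global has wrong length");
  if (chunk_edges < 1) chunk_edges = 1;
  LooMoments M(V);
  const double m = n - 1.0;

  // per-sample downdated first moments and inverse sds, precomputed once
  arma::mat D1(n, r), IS(n, r), Vt(n, r);
  for (int i = 0; i < r; ++i)
    for (int s = 0; s < n; ++s) {
      const double v = V(s, i);
      const double d = M.s1[i] - v;
      const double var = M.S2[(size_t)i * r + i] - v * v - d * d / m;
      if (var <= 0.0)
        stop("zero-variance feature %d when leaving out sample %d", i + 1, s + 1);
      D1(s, i) = d;
      IS(s, i) = 1.0 / std::sqrt(var);
      Vt(s, i) = v;
    }

  arma::mat G(n, n, arma::fill::zeros);
  arma::mat A;
  R_xlen_t e0 = 0;
  int ci = 0, cj = 1;  // pair of edge index 0 in lexicographic order
  while (e0 < k) {
    const R_xlen_t len = std::min(chunk_edges, k - e0);
    A.set_size(n, len);
    for (R_xlen_t t = 0; t < len; ++t) {
      const double S2ij = M.S2[(size_t)ci * r + cj];
      const double cg = c_global[e0 + t];
      double *col = A.colptr(t);
      for (int s = 0; s < n; ++s) {
        const double cov = (S2ij - Vt(s, ci) * Vt(s, cj)) -
          D1(s, ci) * D1(s, cj) / m;
        col[s] = std::fabs(cg - cov * IS(s, ci) * IS(s, cj));
      }
      if (++cj == r) { ++ci; cj = ci + 1; }
    }
    G += A * A.t();
    e0 += len;
    Rcpp::checkUserInterrupt();
  }
  NumericMatrix D(n, n);
  for (int s = 0; s < n; ++s)
    for (int t = 0; t < n; ++t) {
      if (s == t) { D(s, t) = 0.0; continue; }
      double d2 = G(s, s) + G(t, t) - 2.0 * G(s, t);
      D(s, t) = d2 > 0 ? std::sqrt(d2) : 0.0;
    }
  return D;
}
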