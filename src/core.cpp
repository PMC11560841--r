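// Inner loops of the per-cell matrix pipeline. Semantics mirror the
// documented R-level contracts; the test suite checks them against
// brute-force enumeration.
#include <Rcpp.h>
using namespace Rcpp;

extern "C" {
  void sgesv_(const int* n, const int* nrhs, float* a, const int* lda,
              int* ipiv, float* b, const int* ldb, int* info);
}

// Random-walk-with-restart stationary solution on the row-normalized
// matrix: Q = restart * (I - (1-restart) P)^{-1}, symmetrized. Solved in
// single precision (the iteration it replaces has a 1e-2 tolerance).
// [[Rcpp::export]]
NumericMatrix rwr_impute_cpp(const NumericMatrix& B, double restart) {
  const int n = B.nrow();
  std::vector<float> A((size_t)n * n), X((size_t)n * n, 0.0f);
  std::vector<double> rs(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += B(i, j);
    rs[i] = s > 0 ? s : 1.0;
  }
  const double w = 1.0 - restart;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      A[(size_t)j * n + i] = (i == j ? 1.0f : 0.0f) -
        (float)(w * B(i, j) / rs[i]);
  for (int i = 0; i < n; ++i) X[(size_t)i * n + i] = (float)restart;
  std::vector<int> ipiv(n);
  int info = 0;
  sgesv_(&n, &n, A.data(), &n, ipiv.data(), X.data(), &n, &info);
  if (info != 0) stop("sgesv failed (info = %d)", info);
  NumericMatrix Q(n, n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i <= j; ++i) {
      double v = 0.5 * ((double)X[(size_t)j * n + i] +
                        (double)X[(size_t)i * n + j]);
      if (v < 0) v = 0;
      Q(i, j) = v;
      Q(j, i) = v;
    }
  return Q;
}

// Clipped-window box sum of radius r (summed-area table).
// [[Rcpp::export]]
NumericMatrix box_sum_cpp(const NumericMatrix& M, int r) {
  const int n = M.nrow(), m = M.ncol();
  std::vector<double> C((size_t)(n + 1) * (m + 1), 0.0);
  const size_t W = m + 1;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j)
      C[i * W + j] = M(i - 1, j - 1) + C[(i - 1) * W + j] + C[i * W + j - 1] -
        C[(i - 1) * W + j - 1];
  NumericMatrix out(n, m);
  for (int i = 0; i < n; ++i) {
    const int a = std::max(0, i - r), b = std::min(n - 1, i + r);
    for (int j = 0; j < m; ++j) {
      const int c = std::max(0, j - r), d = std::min(m - 1, j + r);
      out(i, j) = C[(b + 1) * W + (d + 1)] - C[a * W + (d + 1)] -
        C[(b + 1) * W + c] + C[a * W + c];
    }
  }
  return out;
}

// Band (D+1 x n, row d+1 = diagonal d) -> dense symmetric matrix.
// [[Rcpp::export]]
NumericMatrix band_to_dense_cpp(const NumericMatrix& B, double fill) {
  const int D = B.nrow() - 1, n = B.ncol();
  NumericMatrix M(n, n);
  std::fill(M.begin(), M.end(), fill);
  for (int d = 0; d <= D; ++d)
    for (int i = 0; i + d < n; ++i) {
      const double v = B(d, i);
      M(i, i + d) = v;
      M(i + d, i) = v;
    }
  return M;
}

// Dense symmetric matrix -> band of max offset D.
// [[Rcpp::export]]
NumericMatrix dense_to_band_cpp(const NumericMatrix& M, int D) {
  const int n = M.nrow();
  NumericMatrix B(D + 1, n);
  std::fill(B.begin(), B.end(), NA_REAL);
  for (int d = 0; d <= D; ++d)
    for (int i = 0; i + d < n; ++i)
      B(d, i) = M(i, i + d);
  return B;
}

// Subtract the mean over the Chebyshev ring inner < r < outer from each
// band entry; ring positions outside the matrix or band are skipped.
// Implemented as box-sum differences on the dense symmetric expansion via
// summed-area tables (value and validity mask).
// [[Rcpp::export]]
NumericMatrix ring_subtract_cpp(const NumericMatrix& B, int inner, int outer) {
  const int D = B.nrow() - 1, n = B.ncol();
  const int H = D + 1;
  const double* bp = B.begin();
  const size_t W = n + 1;
  std::vector<double> Cx(W * W, 0.0);
  std::vector<double> Cw(W * W, 0.0);
  // prefix sums of the dense symmetric matrix (NaN/out-of-band -> 0 with
  // mask 0)
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= n; ++j) {
      const int r = i - 1, c = j - 1;
      int dd = c - r, lo = r;
      if (dd < 0) { dd = -dd; lo = c; }
      double v = 0.0, w = 0.0;
      if (dd <= D) {
        const double x = bp[(size_t)lo * H + dd];
        if (!ISNAN(x)) { v = x; w = 1.0; }
      }
      Cx[i * W + j] = v + Cx[(i - 1) * W + j] + Cx[i * W + j - 1] -
        Cx[(i - 1) * W + j - 1];
      Cw[i * W + j] = w + Cw[(i - 1) * W + j] + Cw[i * W + j - 1] -
        Cw[(i - 1) * W + j - 1];
    }
  const int rO = outer - 1, rI = inner;
  NumericMatrix out(H, n);
  std::fill(out.begin(), out.end(), NA_REAL);
  double* op = out.begin();
  for (int d = 0; d <= D; ++d)
    for (int i = 0; i + d < n; ++i) {
      const int j = i + d;
      const int aO = std::max(0, i - rO), bO = std::min(n - 1, i + rO);
      const int cO = std::max(0, j - rO), dO = std::min(n - 1, j + rO);
      const int aI = std::max(0, i - rI), bI = std::min(n - 1, i + rI);
      const int cI = std::max(0, j - rI), dI = std::min(n - 1, j + rI);
      const double sO = Cx[(bO + 1) * W + dO + 1] - Cx[aO * W + dO + 1] -
        Cx[(bO + 1) * W + cO] + Cx[aO * W + cO];
      const double sI = Cx[(bI + 1) * W + dI + 1] - Cx[aI * W + dI + 1] -
        Cx[(bI + 1) * W + cI] + Cx[aI * W + cI];
      const double wO = Cw[(bO + 1) * W + dO + 1] - Cw[aO * W + dO + 1] -
        Cw[(bO + 1) * W + cO] + Cw[aO * W + cO];
      const double wI = Cw[(bI + 1) * W + dI + 1] - Cw[aI * W + dI + 1] -
        Cw[(bI + 1) * W + cI] + Cw[aI * W + cI];
      const double s = sO - sI, w = wO - wI;
      op[(size_t)i * H + d] = bp[(size_t)i * H + d] -
        (w > 0.5 ? s / w : 0.0);
    }
  return out;
}

// Insulation score: mean of Q over pairs (i, j), b-w <= i <= b < j <= b+w,
// clipped at the ends; NA band entries are skipped.
// [[Rcpp::export]]
NumericVector insulation_cpp(const NumericMatrix& B, int window) {
  const int D = B.nrow() - 1, n = B.ncol();
  NumericVector out(n, NA_REAL);
  for (int b = 0; b + 1 < n; ++b) {
    double s = 0.0;
    int c = 0;
    const int i1 = std::max(0, b - window), j2 = std::min(n - 1, b + window);
    for (int i = i1; i <= b; ++i)
      for (int j = b + 1; j <= j2; ++j) {
        const int d = j - i;
        if (d > D) continue;
        const double v = B(d, i);
        if (NumericVector::is_na(v)) continue;
        s += v;
        ++c;
      }
    if (c > 0) out[b] = s / c;
  }
  return out;
}
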