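#include <Rcpp.h>
using namespace Rcpp;

// DCOL of every row of x against one sample order (1-based).
// [[Rcpp::export]]
NumericVector cpp_dcol_rows(const NumericMatrix& x, const IntegerVector& ord) {
  const int p = x.nrow(), n = x.ncol();
  NumericVector out(p);
  const double* X = REAL(x);
  double* o = REAL(out);
  for (int j = 1; j < n; ++j) {
    const double* a = X + (size_t)p * (ord[j - 1] - 1);
    const double* b = X + (size_t)p * (ord[j] - 1);
    for (int i = 0; i < p; ++i) o[i] += std::fabs(b[i] - a[i]);
  }
  const double denom = n - 1;
  for (int i = 0; i < p; ++i) o[i] /= denom;
  return out;
}

// Greedy nearest-neighbor open path from `start` (1-based in and out);
// ties go to the lowest sample index.
// [[Rcpp::export]]
IntegerVector cpp_nn_path(const NumericMatrix& d, int start) {
  const int n = d.nrow();
  const double* D = REAL(d);
  IntegerVector path(n);
  std::vector<bool> used(n, false);
  int cur = start - 1;
  path[0] = start;
  used[cur] = true;
  for (int step = 1; step < n; ++step) {
    const double* col = D + (size_t)n * cur;  // d is symmetric
    int nxt = -1;
    double best = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (!used[j] && col[j] < best) {
        best = col[j];
        nxt = j;
      }
    }
    path[step] = nxt + 1;
    used[nxt] = true;
    cur = nxt;
  }
  return path;
}

// 2-opt descent for an open path: repeatedly reverse the segment whose
// reversal shortens the path most (per anchor position i), until a full
// pass yields no strictly improving reversal.  Reversing positions i..j
// replaces edges (i-1,i) and (j,j+1) by (i-1,j) and (i,j+1); a missing
// boundary edge (i = first or j = last position) contributes nothing.
// [[Rcpp::export]]
IntegerVector cpp_two_opt(const NumericMatrix& d, const IntegerVector& path0,
                          double tol) {
  const int n = path0.size();
  IntegerVector path = clone(path0);
  if (n < 3) return path;
  const double* D = REAL(d);
  const size_t N = d.nrow();
  bool improved = true;
  while (improved) {
    improved = false;
    for (int i = 0; i < n - 1; ++i) {
      const int prev = (i > 0) ? path[i - 1] - 1 : -1;
      const int pi = path[i] - 1;
      const double* rowPrev = (prev >= 0) ? D + N * prev : nullptr;
      const double* rowPi = D + N * pi;
      const double basePrev = (prev >= 0) ? rowPrev[pi] : 0.0;
      double best = 0.0;
      int bestj = -1;
      for (int j = i + 1; j < n; ++j) {
        const int pj = path[j] - 1;
        double delta = rowPrev ? (rowPrev[pj] - basePrev) : 0.0;
        if (j < n - 1) {
          const int nxt = path[j + 1] - 1;
          delta += rowPi[nxt] - D[N * pj + nxt];
        }
        if (delta < best) {
          best = delta;
          bestj = j;
        }
      }
      if (bestj >= 0 && best < -tol) {
        std::reverse(path.begin() + i, path.begin() + bestj + 1);
        improved = true;
      }
    }
  }
  return path;
}

// Euclidean distances between sample columns restricted to `rows`
// (1-based gene indices).
// [[Rcpp::export]]
NumericMatrix cpp_sample_dist(const NumericMatrix& x, const IntegerVector& rows) {
  const int n = x.ncol(), m = rows.size(), p = x.nrow();
  const double* X = REAL(x);
  // gather the subspace into a compact samples x genes buffer so the
  // pairwise pass is cache-friendly
  std::vector<double> sub((size_t)n * m);
  for (int a = 0; a < n; ++a) {
    const double* col = X + (size_t)p * a;
    double* dst = sub.data() + (size_t)m * a;
    for (int r = 0; r < m; ++r) dst[r] = col[rows[r] - 1];
  }
  NumericMatrix out(n, n);
  double* O = REAL(out);
  for (int a = 0; a < n; ++a) {
    const double* va = sub.data() + (size_t)m * a;
    for (int b = a + 1; b < n; ++b) {
      const double* vb = sub.data() + (size_t)m * b;
      double s = 0.0;
      for (int r = 0; r < m; ++r) {
        const double diff = va[r] - vb[r];
        s += diff * diff;
      }
      const double v = std::sqrt(s);
      O[(size_t)n * b + a] = v;
      O[(size_t)n * a + b] = v;
    }
  }
  return out;
}
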