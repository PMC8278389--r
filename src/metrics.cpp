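#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double periodic_diff1(double a, double b) {
  double d = std::fabs(a - b);
  if (d > M_PI) d = 2.0 * M_PI - d;
  return d;
}

// Pairwise barrier-weighted periodic distances.
// form = 0: weighted Euclidean  sqrt(sum (w_n d_n)^2)
// form = 1: weighted Manhattan  sum w_n d_n
// Frames are transposed into a contiguous m x n buffer and processed in
// blocks of rows, so peak working memory beyond the output matrix is
// proportional to the block size, not N^2.
// [[Rcpp::export(name = ".cpp_distance_matrix")]]
NumericMatrix cpp_distance_matrix(const NumericMatrix& angles,
                                  const NumericVector& w,
                                  int form,
                                  int block_size) {
  const int n = angles.nrow();
  const int m = angles.ncol();
  if (w.size() != m) stop("weight length mismatch");
  std::vector<double> at(static_cast<size_t>(n) * m);  // frame-major
  for (int k = 0; k < m; ++k)
    for (int i = 0; i < n; ++i)
      at[static_cast<size_t>(i) * m + k] = angles(i, k);
  NumericMatrix D(n, n);
  double* d = REAL(D);
  if (block_size < 1) block_size = 1024;
  for (int bi = 0; bi < n; bi += block_size) {
    int bend = std::min(n, bi + block_size);
    for (int i = bi; i < bend; ++i) {
      const double* ai = &at[static_cast<size_t>(i) * m];
      for (int j = i + 1; j < n; ++j) {
        const double* aj = &at[static_cast<size_t>(j) * m];
        double acc = 0.0;
        for (int k = 0; k < m; ++k) {
          double dd = periodic_diff1(ai[k], aj[k]) * w[k];
          acc += (form == 0) ? dd * dd : dd;
        }
        double dij = (form == 0) ? std::sqrt(acc) : acc;
        d[static_cast<size_t>(j) * n + i] = dij;
        d[static_cast<size_t>(i) * n + j] = dij;
      }
    }
  }
  return D;
}

// rho_i = #{ j != i : d_ij < d_c }, strict inequality. Column scans on
// the symmetric matrix keep access contiguous.
// [[Rcpp::export(name = ".cpp_density")]]
IntegerVector cpp_density(const NumericMatrix& D, double d_c) {
  const int n = D.nrow();
  const double* d = REAL(D);
  IntegerVector rho(n);
  for (int i = 0; i < n; ++i) {
    const double* col = d + static_cast<size_t>(i) * n;
    int c = 0;
    for (int j = 0; j < n; ++j)
      if (col[j] < d_c) ++c;
    rho[i] = c - 1;  // the zero diagonal counted itself
  }
  return rho;
}

// delta_i = distance to the nearest point of higher density, with density
// ties broken by index (lower index counts as denser). `ord` is the
// 1-based precedence order: ord[0] is the densest point, which receives
// delta = max_j d_ij and nearest_higher = NA.
// [[Rcpp::export(name = ".cpp_delta")]]
List cpp_delta(const NumericMatrix& D, const IntegerVector& ord) {
  const int n = D.nrow();
  const double* d = REAL(D);
  NumericVector delta(n);
  IntegerVector nearest(n);
  for (int r = 0; r < n; ++r) {
    int i = ord[r] - 1;
    const double* col = d + static_cast<size_t>(i) * n;  // symmetric
    if (r == 0) {
      double mx = 0.0;
      for (int j = 0; j < n; ++j) if (col[j] > mx) mx = col[j];
      delta[i] = mx;
      nearest[i] = NA_INTEGER;
    } else {
      double mn = R_PosInf;
      int arg = NA_INTEGER;
      for (int s = 0; s < r; ++s) {
        int j = ord[s] - 1;
        if (col[j] < mn) { mn = col[j]; arg = j + 1; }
      }
      delta[i] = mn;
      nearest[i] = arg;
    }
  }
  return List::create(_["delta"] = delta, _["nearest_higher"] = nearest);
}

// number of off-diagonal pairs with d < x (upper triangle count)
// [[Rcpp::export(name = ".cpp_count_below")]]
double cpp_count_below(const NumericMatrix& D, double x) {
  const int n = D.nrow();
  const double* d = REAL(D);
  double cnt = 0;
  for (int j = 1; j < n; ++j) {
    const double* col = d + static_cast<size_t>(j) * n;
    for (int i = 0; i < j; ++i)
      if (col[i] < x) ++cnt;
  }
  return cnt;
}
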