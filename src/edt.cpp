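#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1D squared distance transform, lower envelope of parabolas
// (Felzenszwalb & Huttenlocher).  f: strided input squared distances,
// d: dense output buffer of length n.
static void dt1d(const double* f, double* d, int n, int stride) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double fq = f[q * stride];
    double s;
    while (true) {
      double fv = f[v[k] * stride];
      s = ((fq + (double)q * q) - (fv + (double)v[k] * v[k])) / (2.0 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k] * stride];
  }
}

// [[Rcpp::export(name = ".cpp_edt3d")]]
NumericVector cpp_edt3d(LogicalVector sites, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  const double INF = 1e30;
  NumericVector out(N);
  double* d = REAL(out);
  for (R_xlen_t i = 0; i < N; ++i)
    d[i] = (sites[i] == TRUE) ? 0.0 : INF;
  std::vector<double> tmp((size_t)std::max(n1, std::max(n2, n3)));

  // axis 1 (fastest varying)
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      double* col = d + (R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1;
      dt1d(col, tmp.data(), n1, 1);
      for (int i = 0; i < n1; ++i) col[i] = tmp[i];
    }
  // axis 2 (stride n1)
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      double* col = d + (R_xlen_t)k * n1 * n2 + i;
      dt1d(col, tmp.data(), n2, n1);
      for (int j = 0; j < n2; ++j) col[(R_xlen_t)j * n1] = tmp[j];
    }
  // axis 3
  const R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      double* col = d + (R_xlen_t)j * n1 + i;
      dt1d(col, tmp.data(), n3, s3);
      for (int k = 0; k < n3; ++k) col[k * s3] = tmp[k];
    }
  for (R_xlen_t i = 0; i < N; ++i) d[i] = std::sqrt(d[i]);
  return out;
}
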