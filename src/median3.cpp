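#include <Rcpp.h>
using namespace Rcpp;

// Binary median (majority) filter with odd cubic window; the window is
// clipped at the volume border and ties keep the centre value.
// [[Rcpp::export(name = ".cpp_median_binary")]]
LogicalVector cpp_median_binary(LogicalVector mask, IntegerVector dims,
                                int window) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int r = window / 2;
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  LogicalVector out(N);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int cnt = 0, tot = 0;
        for (int dk = -r; dk <= r; ++dk) {
          int kk = k + dk; if (kk < 0 || kk >= n3) continue;
          for (int dj = -r; dj <= r; ++dj) {
            int jj = j + dj; if (jj < 0 || jj >= n2) continue;
            for (int di = -r; di <= r; ++di) {
              int ii = i + di; if (ii < 0 || ii >= n1) continue;
              ++tot;
              if (mask[(R_xlen_t)kk * n1 * n2 + (R_xlen_t)jj * n1 + ii] == TRUE)
                ++cnt;
            }
          }
        }
        R_xlen_t v = (R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1 + i;
        if (2 * cnt > tot) out[v] = TRUE;
        else if (2 * cnt < tot) out[v] = FALSE;
        else out[v] = mask[v];
      }
  return out;
}
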