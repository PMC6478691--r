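#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Multi-source BFS geodesic distance (6-connectivity) from `seeds`
// through `allowed` voxels; -1 where unreachable or not allowed.
// [[Rcpp::export(name = ".cpp_geodesic")]]
IntegerVector cpp_geodesic(LogicalVector allowed, LogicalVector seeds,
                           IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  IntegerVector out(N, -1);
  std::queue<R_xlen_t> q;
  for (R_xlen_t v = 0; v < N; ++v)
    if (seeds[v] == TRUE && allowed[v] == TRUE) {
      out[v] = 0;
      q.push(v);
    }
  const int d1[6] = {1, -1, 0, 0, 0, 0};
  const int d2[6] = {0, 0, 1, -1, 0, 0};
  const int d3[6] = {0, 0, 0, 0, 1, -1};
  while (!q.empty()) {
    R_xlen_t v = q.front(); q.pop();
    int i = (int)(v % n1);
    int j = (int)((v / n1) % n2);
    int k = (int)(v / ((R_xlen_t)n1 * n2));
    int dv = out[v];
    for (int t = 0; t < 6; ++t) {
      int ii = i + d1[t], jj = j + d2[t], kk = k + d3[t];
      if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
        continue;
      R_xlen_t w = (R_xlen_t)kk * n1 * n2 + (R_xlen_t)jj * n1 + ii;
      if (allowed[w] == TRUE && out[w] < 0) {
        out[w] = dv + 1;
        q.push(w);
      }
    }
  }
  return out;
}
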