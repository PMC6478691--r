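#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a 3D logical mask.
// connectivity: 6 (face) or 26 (face/edge/corner).
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(N);
  std::vector<R_xlen_t> stack;
  // neighbour offsets
  std::vector<int> d1, d2, d3;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int m = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (m == 0) continue;
        if (connectivity == 6 && m != 1) continue;
        d1.push_back(di); d2.push_back(dj); d3.push_back(dk);
      }
  const int nn = (int)d1.size();
  int cur = 0;
  for (R_xlen_t s = 0; s < N; ++s) {
    if (mask[s] != TRUE || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int i = (int)(v % n1);
      int j = (int)((v / n1) % n2);
      int k = (int)(v / ((R_xlen_t)n1 * n2));
      for (int t = 0; t < nn; ++t) {
        int ii = i + d1[t], jj = j + d2[t], kk = k + d3[t];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
          continue;
        R_xlen_t w = (R_xlen_t)kk * n1 * n2 + (R_xlen_t)jj * n1 + ii;
        if (mask[w] == TRUE && lab[w] == 0) {
          lab[w] = cur;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}
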