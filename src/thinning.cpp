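#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Topology-preserving 3D thinning to a 1-voxel-wide curve skeleton.
//
// A voxel is deletable when it is "simple" in the (26, 6) digital-topology
// sense (Malandain & Bertrand characterisation):
//   (a) the foreground restricted to its 26-neighbourhood (centre excluded)
//       has exactly one 26-connected component, and
//   (b) the background restricted to its 18-neighbourhood has exactly one
//       6-connected component that is 6-adjacent to the centre.
// Curve endpoints (<= 1 foreground 26-neighbour) are preserved.  Deletion
// proceeds in six directional sub-iterations; within each, candidates are
// re-checked sequentially so that simultaneous removal cannot alter
// topology (as in Lee et al.-style thinning).

static inline int idx3(int i, int j, int k, int n1, int n2) {
  return k * n1 * n2 + j * n1 + i;
}

// local 3x3x3 cube: position p = (di+1) + 3*(dj+1) + 9*(dk+1), centre p=13
static const int C = 13;

static int n26_count(const std::vector<char>& cube) {
  int c = 0;
  for (int p = 0; p < 27; ++p)
    if (p != C && cube[p]) ++c;
  return c;
}

// number of 26-connected foreground components in N26 (centre excluded)
static int fg_components(const std::vector<char>& cube) {
  char seen[27] = {0};
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == C || !cube[s] || seen[s]) continue;
    ++ncomp;
    int top = 0;
    stack[top++] = s;
    seen[s] = 1;
    while (top) {
      int v = stack[--top];
      int vi = v % 3, vj = (v / 3) % 3, vk = v / 9;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = vi + di, jj = vj + dj, kk = vk + dk;
            if (ii < 0 || ii > 2 || jj < 0 || jj > 2 || kk < 0 || kk > 2)
              continue;
            int w = kk * 9 + jj * 3 + ii;
            if (w == C || !cube[w] || seen[w]) continue;
            seen[w] = 1;
            stack[top++] = w;
          }
    }
  }
  return ncomp;
}

// number of 6-connected background components in N18 that touch the centre
// through a face
static int bg_components(const std::vector<char>& cube) {
  // N18 membership: |di|+|dj|+|dk| <= 2, not centre
  char in18[27], seen[27] = {0};
  for (int p = 0; p < 27; ++p) {
    int di = p % 3 - 1, dj = (p / 3) % 3 - 1, dk = p / 9 - 1;
    int m = std::abs(di) + std::abs(dj) + std::abs(dk);
    in18[p] = (m >= 1 && m <= 2);
  }
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (!in18[s] || cube[s] || seen[s]) continue;
    // grow the 6-connected background component within N18
    bool touches = false;
    int top = 0;
    stack[top++] = s;
    seen[s] = 1;
    while (top) {
      int v = stack[--top];
      int vi = v % 3, vj = (v / 3) % 3, vk = v / 9;
      int m = std::abs(vi - 1) + std::abs(vj - 1) + std::abs(vk - 1);
      if (m == 1) touches = true;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int t = 0; t < 6; ++t) {
        int ii = vi + d6[t][0], jj = vj + d6[t][1], kk = vk + d6[t][2];
        if (ii < 0 || ii > 2 || jj < 0 || jj > 2 || kk < 0 || kk > 2) continue;
        int w = kk * 9 + jj * 3 + ii;
        if (!in18[w] || cube[w] || seen[w]) continue;
        seen[w] = 1;
        stack[top++] = w;
      }
    }
    if (touches) ++ncomp;
  }
  return ncomp;
}

static void fill_cube(const std::vector<char>& img, std::vector<char>& cube,
                      int i, int j, int k, int n1, int n2, int n3) {
  int p = 0;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di, ++p) {
        int ii = i + di, jj = j + dj, kk = k + dk;
        cube[p] = (ii >= 0 && ii < n1 && jj >= 0 && jj < n2 &&
                   kk >= 0 && kk < n3)
                    ? img[idx3(ii, jj, kk, n1, n2)]
                    : 0;
      }
}

static bool is_simple(const std::vector<char>& cube) {
  return fg_components(cube) == 1 && bg_components(cube) == 1;
}

// [[Rcpp::export(name = ".cpp_thin3d")]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  std::vector<char> img(N);
  for (R_xlen_t v = 0; v < N; ++v) img[v] = (mask[v] == TRUE);

  const int dir[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  std::vector<char> cube(27);
  std::vector<int> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int k = 0; k < n3; ++k)
        for (int j = 0; j < n2; ++j)
          for (int i = 0; i < n1; ++i) {
            int v = idx3(i, j, k, n1, n2);
            if (!img[v]) continue;
            // border in direction d: face neighbour is background/outside
            int ii = i + dir[d][0], jj = j + dir[d][1], kk = k + dir[d][2];
            bool borderd = !(ii >= 0 && ii < n1 && jj >= 0 && jj < n2 &&
                             kk >= 0 && kk < n3) ||
                           !img[idx3(ii, jj, kk, n1, n2)];
            if (!borderd) continue;
            fill_cube(img, cube, i, j, k, n1, n2, n3);
            if (n26_count(cube) <= 1) continue;  // endpoint
            if (is_simple(cube)) cand.push_back(v);
          }
      // sequential re-checked deletion
      for (size_t t = 0; t < cand.size(); ++t) {
        int v = cand[t];
        int i = v % n1, j = (v / n1) % n2, k = v / (n1 * n2);
        fill_cube(img, cube, i, j, k, n1, n2, n3);
        if (n26_count(cube) <= 1) continue;
        if (is_simple(cube)) {
          img[v] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(N);
  for (R_xlen_t v = 0; v < N; ++v) out[v] = img[v] ? TRUE : FALSE;
  return out;
}
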