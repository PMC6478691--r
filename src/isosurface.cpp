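#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Isosurface area of a binary volume at the 0.5 level by marching
// tetrahedra: each 2x2x2 voxel cell is split into six tetrahedra around
// the main diagonal and the level set is triangulated with edge-midpoint
// crossings (binary data).  The volume is implicitly zero-padded so that
// surfaces at the border are closed.  An optional pre-smoothing (mean
// over the 2x2x2 sample values is NOT applied here; smoothing, when
// requested, happens on the R side) keeps this kernel exact.

struct V3 { double x, y, z; };

static inline V3 mid(const V3& a, const V3& b) {
  V3 m = {0.5 * (a.x + b.x), 0.5 * (a.y + b.y), 0.5 * (a.z + b.z)};
  return m;
}
static inline double triarea(const V3& a, const V3& b, const V3& c) {
  double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
  double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
  double cx = uy * vz - uz * vy;
  double cy = uz * vx - ux * vz;
  double cz = ux * vy - uy * vx;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// crossing point on a tet edge between sample points with values va, vb
// (one inside >= iso, one outside) at positions a, b; linear interpolation.
static inline V3 crossing(const V3& a, const V3& b, double va, double vb,
                          double iso) {
  double t = (iso - va) / (vb - va);
  V3 p = {a.x + t * (b.x - a.x), a.y + t * (b.y - a.y), a.z + t * (b.z - a.z)};
  return p;
}

// [[Rcpp::export(name = ".cpp_isosurface_area")]]
double cpp_isosurface_area(NumericVector field, IntegerVector dims,
                           double iso) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  // six tetrahedra around the 0-7 diagonal of the unit cube
  // cube vertex numbering: bit0 -> +i, bit1 -> +j, bit2 -> +k
  static const int tets[6][4] = {
    {0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
    {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}};
  double total = 0.0;
  // iterate cube corners from -1..n (zero padding outside)
  for (int k = -1; k < n3; ++k)
    for (int j = -1; j < n2; ++j)
      for (int i = -1; i < n1; ++i) {
        double val[8];
        V3 pos[8];
        bool any = false, all = true;
        for (int c = 0; c < 8; ++c) {
          int ii = i + (c & 1), jj = j + ((c >> 1) & 1), kk = k + ((c >> 2) & 1);
          double v = 0.0;
          if (ii >= 0 && ii < n1 && jj >= 0 && jj < n2 && kk >= 0 && kk < n3)
            v = field[(R_xlen_t)kk * n1 * n2 + (R_xlen_t)jj * n1 + ii];
          val[c] = v;
          pos[c].x = ii; pos[c].y = jj; pos[c].z = kk;
          if (v >= iso) any = true; else all = false;
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          int a = tets[t][0], b = tets[t][1], c = tets[t][2], d = tets[t][3];
          int vs[4] = {a, b, c, d};
          int ins[4], outs[4], ni = 0, no = 0;
          for (int q = 0; q < 4; ++q) {
            if (val[vs[q]] >= iso) ins[ni++] = vs[q];
            else outs[no++] = vs[q];
          }
          if (ni == 0 || ni == 4) continue;
          if (ni == 1 || ni == 3) {
            int apex = (ni == 1) ? ins[0] : outs[0];
            int* base = (ni == 1) ? outs : ins;
            V3 p1 = crossing(pos[apex], pos[base[0]], val[apex], val[base[0]], iso);
            V3 p2 = crossing(pos[apex], pos[base[1]], val[apex], val[base[1]], iso);
            V3 p3 = crossing(pos[apex], pos[base[2]], val[apex], val[base[2]], iso);
            total += triarea(p1, p2, p3);
          } else {
            // quad: edges (i0,o0),(i0,o1),(i1,o1),(i1,o0) in cyclic order
            V3 q1 = crossing(pos[ins[0]], pos[outs[0]], val[ins[0]], val[outs[0]], iso);
            V3 q2 = crossing(pos[ins[0]], pos[outs[1]], val[ins[0]], val[outs[1]], iso);
            V3 q3 = crossing(pos[ins[1]], pos[outs[1]], val[ins[1]], val[outs[1]], iso);
            V3 q4 = crossing(pos[ins[1]], pos[outs[0]], val[ins[1]], val[outs[0]], iso);
            total += triarea(q1, q2, q3) + triarea(q1, q3, q4);
          }
        }
      }
  return total;
}
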