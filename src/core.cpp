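// 3D raster primitives for anisotropic confocal stacks.
// All arrays use R dim = c(nz, ny, nx); linear index = z + nz*(y + ny*x), 0-based.
#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

struct Grid {
  int nz, ny, nx;
  Grid(IntegerVector d) : nz(d[0]), ny(d[1]), nx(d[2]) {}
  inline long size() const { return (long)nz * ny * nx; }
  inline long lin(int z, int y, int x) const { return z + (long)nz * (y + (long)ny * x); }
  inline bool in(int z, int y, int x) const {
    return z >= 0 && z < nz && y >= 0 && y < ny && x >= 0 && x < nx;
  }
};

// 26-neighborhood offsets (excluding the center)
static const int NB26[26][3] = {
  {-1,-1,-1},{-1,-1,0},{-1,-1,1},{-1,0,-1},{-1,0,0},{-1,0,1},{-1,1,-1},{-1,1,0},{-1,1,1},
  { 0,-1,-1},{ 0,-1,0},{ 0,-1,1},{ 0,0,-1},          { 0,0,1},{ 0,1,-1},{ 0,1,0},{ 0,1,1},
  { 1,-1,-1},{ 1,-1,0},{ 1,-1,1},{ 1,0,-1},{ 1,0,0},{ 1,0,1},{ 1,1,-1},{ 1,1,0},{ 1,1,1}
};
static const int NB6[6][3] = {
  {-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}
};

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims, int connectivity) {
  Grid g(dims);
  IntegerVector lab(mask.size(), 0);
  const int nnb = (connectivity == 26) ? 26 : 6;
  int next = 0;
  std::vector<long> stack;
  for (int x = 0; x < g.nx; ++x) for (int y = 0; y < g.ny; ++y) for (int z = 0; z < g.nz; ++z) {
    long i = g.lin(z, y, x);
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      long c = stack.back(); stack.pop_back();
      int cz = c % g.nz, cy = (c / g.nz) % g.ny, cx = c / ((long)g.nz * g.ny);
      for (int k = 0; k < nnb; ++k) {
        int dz, dy, dx;
        if (connectivity == 26) { dz = NB26[k][0]; dy = NB26[k][1]; dx = NB26[k][2]; }
        else { dz = NB6[k][0]; dy = NB6[k][1]; dx = NB6[k][2]; }
        int z2 = cz + dz, y2 = cy + dy, x2 = cx + dx;
        if (!g.in(z2, y2, x2)) continue;
        long j = g.lin(z2, y2, x2);
        if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  return lab;
}

// Fill interior cavities: background 6-components not reaching the border become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dims) {
  Grid g(dims);
  std::vector<char> outside(g.size(), 0);
  std::vector<long> stack;
  // seed: all background border voxels
  for (int x = 0; x < g.nx; ++x) for (int y = 0; y < g.ny; ++y) for (int z = 0; z < g.nz; ++z) {
    if (z != 0 && z != g.nz - 1 && y != 0 && y != g.ny - 1 && x != 0 && x != g.nx - 1) continue;
    long i = g.lin(z, y, x);
    if (!mask[i] && !outside[i]) { outside[i] = 1; stack.push_back(i); }
  }
  while (!stack.empty()) {
    long c = stack.back(); stack.pop_back();
    int cz = c % g.nz, cy = (c / g.nz) % g.ny, cx = c / ((long)g.nz * g.ny);
    for (int k = 0; k < 6; ++k) {
      int z2 = cz + NB6[k][0], y2 = cy + NB6[k][1], x2 = cx + NB6[k][2];
      if (!g.in(z2, y2, x2)) continue;
      long j = g.lin(z2, y2, x2);
      if (!mask[j] && !outside[j]) { outside[j] = 1; stack.push_back(j); }
    }
  }
  LogicalVector out(mask.size());
  for (long i = 0; i < (long)mask.size(); ++i) out[i] = mask[i] || !outside[i];
  return out;
}

// Grayscale erosion/dilation over an arbitrary offset set (rows: dz, dy, dx).
// Out-of-bounds offsets are ignored (border handled by shrinking the window).
// Offset-outer formulation: for each offset the update is a shifted-array
// min/max over a contiguous z-span, which keeps memory access sequential.
// Out-of-bounds offsets are ignored (window shrinks at the border).
// [[Rcpp::export]]
NumericVector cpp_grey_morph(NumericVector vol, IntegerVector dims, IntegerMatrix offsets, bool dilate) {
  Grid g(dims);
  NumericVector out(vol.size(), dilate ? R_NegInf : R_PosInf);
  int no = offsets.nrow();
  for (int k = 0; k < no; ++k) {
    int dz = offsets(k, 0), dy = offsets(k, 1), dx = offsets(k, 2);
    int x0 = std::max(0, -dx), x1 = g.nx - 1 - std::max(0, dx);
    int y0 = std::max(0, -dy), y1 = g.ny - 1 - std::max(0, dy);
    int z0 = std::max(0, -dz), z1 = g.nz - 1 - std::max(0, dz);
    for (int x = x0; x <= x1; ++x) for (int y = y0; y <= y1; ++y) {
      const double* src = &vol[g.lin(z0 + dz, y + dy, x + dx)];
      double* dst = &out[g.lin(z0, y, x)];
      int n = z1 - z0 + 1;
      if (dilate) { for (int i = 0; i < n; ++i) if (src[i] > dst[i]) dst[i] = src[i]; }
      else { for (int i = 0; i < n; ++i) if (src[i] < dst[i]) dst[i] = src[i]; }
    }
  }
  return out;
}

// Binary dilation with an offset set (for lumen-mask dilation).
// [[Rcpp::export]]
LogicalVector cpp_binary_dilate(LogicalVector mask, IntegerVector dims, IntegerMatrix offsets) {
  Grid g(dims);
  LogicalVector out(mask.size(), false);
  int no = offsets.nrow();
  for (int x = 0; x < g.nx; ++x) for (int y = 0; y < g.ny; ++y) for (int z = 0; z < g.nz; ++z) {
    long i = g.lin(z, y, x);
    if (!mask[i]) continue;
    for (int k = 0; k < no; ++k) {
      int z2 = z + offsets(k, 0), y2 = y + offsets(k, 1), x2 = x + offsets(k, 2);
      if (g.in(z2, y2, x2)) out[g.lin(z2, y2, x2)] = true;
    }
  }
  return out;
}

// Separable Gaussian blur, sigma per axis in voxel units; kernel renormalized at borders.
static void blur_axis(std::vector<double>& v, const Grid& g, int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  for (int i = -r; i <= r; ++i) k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
  std::vector<double> out(v.size());
  int n[3] = {g.nz, g.ny, g.nx};
  long stride[3] = {1, g.nz, (long)g.nz * g.ny};
  int na = n[axis];
  long sa = stride[axis];
  // iterate over all lines along `axis`
  int b = (axis == 0) ? 1 : 0;
  int c = (axis == 2) ? 1 : 2;
  std::vector<double> line(na);
  for (int ib = 0; ib < n[b]; ++ib) for (int ic = 0; ic < n[c]; ++ic) {
    long base = ib * stride[b] + ic * stride[c];
    for (int ia = 0; ia < na; ++ia) line[ia] = v[base + ia * sa];
    for (int ia = 0; ia < na; ++ia) {
      double s = 0, w = 0;
      int lo = std::max(-r, -ia), hi = std::min(r, na - 1 - ia);
      for (int d = lo; d <= hi; ++d) { double kk = k[d + r]; s += kk * line[ia + d]; w += kk; }
      out[base + ia * sa] = s / w;
    }
  }
  v.swap(out);
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector vol, IntegerVector dims, NumericVector sigma_vox) {
  Grid g(dims);
  std::vector<double> v(vol.begin(), vol.end());
  for (int a = 0; a < 3; ++a) blur_axis(v, g, a, sigma_vox[a]);
  return NumericVector(v.begin(), v.end());
}

// Rasterize capsules (cylinders with spherical caps) into a label grid.
// segs rows: z0,y0,x0,z1,y1,x1,radius (all um); labels: one per segment.
// Existing nonzero labels are kept (first writer wins).
// [[Rcpp::export]]
IntegerVector cpp_rasterize_tubes(IntegerVector dims, NumericVector spacing, NumericMatrix segs,
                                  IntegerVector labels, IntegerVector init) {
  Grid g(dims);
  IntegerVector lab = (init.size() == (long)g.size()) ? clone(init) : IntegerVector(g.size(), 0);
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  for (int s = 0; s < segs.nrow(); ++s) {
    double az = segs(s, 0), ay = segs(s, 1), ax = segs(s, 2);
    double bz = segs(s, 3), by = segs(s, 4), bx = segs(s, 5);
    double r = segs(s, 6);
    int z0 = std::max(0, (int)std::floor((std::min(az, bz) - r) / sz));
    int z1 = std::min(g.nz - 1, (int)std::ceil((std::max(az, bz) + r) / sz));
    int y0 = std::max(0, (int)std::floor((std::min(ay, by) - r) / sy));
    int y1 = std::min(g.ny - 1, (int)std::ceil((std::max(ay, by) + r) / sy));
    int x0 = std::max(0, (int)std::floor((std::min(ax, bx) - r) / sx));
    int x1 = std::min(g.nx - 1, (int)std::ceil((std::max(ax, bx) + r) / sx));
    double dz = bz - az, dy = by - ay, dx = bx - ax;
    double len2 = dz * dz + dy * dy + dx * dx;
    double r2 = r * r;
    for (int x = x0; x <= x1; ++x) for (int y = y0; y <= y1; ++y) for (int z = z0; z <= z1; ++z) {
      double pz = z * sz, py = y * sy, px = x * sx;
      double t = 0;
      if (len2 > 0) {
        t = ((pz - az) * dz + (py - ay) * dy + (px - ax) * dx) / len2;
        if (t < 0) t = 0; else if (t > 1) t = 1;
      }
      double qz = az + t * dz - pz, qy = ay + t * dy - py, qx = ax + t * dx - px;
      if (qz * qz + qy * qy + qx * qx <= r2) {
        long i = g.lin(z, y, x);
        if (lab[i] == 0) lab[i] = labels[s];
      }
    }
  }
  return lab;
}

// Rasterize an ellipsoid with principal axes (rows of `axes`, unit vectors in (z,y,x) um space).
// [[Rcpp::export]]
LogicalVector cpp_rasterize_ellipsoid(IntegerVector dims, NumericVector spacing, NumericVector center,
                                      NumericMatrix axes, NumericVector semi) {
  Grid g(dims);
  LogicalVector out(g.size(), false);
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  double rmax = std::max(semi[0], std::max(semi[1], semi[2]));
  int z0 = std::max(0, (int)std::floor((center[0] - rmax) / sz));
  int z1 = std::min(g.nz - 1, (int)std::ceil((center[0] + rmax) / sz));
  int y0 = std::max(0, (int)std::floor((center[1] - rmax) / sy));
  int y1 = std::min(g.ny - 1, (int)std::ceil((center[1] + rmax) / sy));
  int x0 = std::max(0, (int)std::floor((center[2] - rmax) / sx));
  int x1 = std::min(g.nx - 1, (int)std::ceil((center[2] + rmax) / sx));
  for (int x = x0; x <= x1; ++x) for (int y = y0; y <= y1; ++y) for (int z = z0; z <= z1; ++z) {
    double d[3] = {z * sz - center[0], y * sy - center[1], x * sx - center[2]};
    double q = 0;
    for (int a = 0; a < 3; ++a) {
      double proj = d[0] * axes(a, 0) + d[1] * axes(a, 1) + d[2] * axes(a, 2);
      q += (proj / semi[a]) * (proj / semi[a]);
    }
    if (q <= 1.0) out[g.lin(z, y, x)] = true;
  }
  return out;
}

// ---- topology-preserving thinning -------------------------------------------------

// Count foreground 26-neighbors.
static inline int count_nb26(const std::vector<char>& m, const Grid& g, int z, int y, int x) {
  int n = 0;
  for (int k = 0; k < 26; ++k) {
    int z2 = z + NB26[k][0], y2 = y + NB26[k][1], x2 = x + NB26[k][2];
    if (g.in(z2, y2, x2) && m[g.lin(z2, y2, x2)]) ++n;
  }
  return n;
}

// Simple-point test (Bertrand & Malandain characterization):
// exactly one 26-component of foreground in N26*, and exactly one 6-component of
// background within the 18-neighborhood that is 6-adjacent to the center.
static bool is_simple(const std::vector<char>& m, const Grid& g, int z, int y, int x) {
  // local 3x3x3 occupancy, center at (1,1,1); out-of-bounds = background
  bool nb[3][3][3];
  for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
    int z2 = z + dz, y2 = y + dy, x2 = x + dx;
    nb[dz + 1][dy + 1][dx + 1] = g.in(z2, y2, x2) && m[g.lin(z2, y2, x2)];
  }
  // --- condition 1: one 26-component of fg among the 26 neighbors
  bool seen[3][3][3] = {{{false}}};
  int ncomp = 0;
  for (int a = 0; a < 26; ++a) {
    int sz0 = NB26[a][0] + 1, sy0 = NB26[a][1] + 1, sx0 = NB26[a][2] + 1;
    if (!nb[sz0][sy0][sx0] || seen[sz0][sy0][sx0]) continue;
    ++ncomp;
    if (ncomp > 1) return false;
    std::vector<int> st;
    st.push_back(sz0 * 9 + sy0 * 3 + sx0);
    seen[sz0][sy0][sx0] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cz = c / 9, cy = (c / 3) % 3, cx = c % 3;
      for (int k = 0; k < 26; ++k) {
        int z2 = cz + NB26[k][0], y2 = cy + NB26[k][1], x2 = cx + NB26[k][2];
        if (z2 < 0 || z2 > 2 || y2 < 0 || y2 > 2 || x2 < 0 || x2 > 2) continue;
        if (z2 == 1 && y2 == 1 && x2 == 1) continue; // exclude the center
        if (nb[z2][y2][x2] && !seen[z2][y2][x2]) { seen[z2][y2][x2] = true; st.push_back(z2 * 9 + y2 * 3 + x2); }
      }
    }
  }
  if (ncomp != 1) return false;
  // --- condition 2: one 6-component of bg within N18, 6-adjacent to center
  // N18 = cells with |dz|+|dy|+|dx| <= 2 (excluding center and the 8 corners)
  bool seenb[3][3][3] = {{{false}}};
  int nbg = 0;
  for (int k = 0; k < 6; ++k) {
    int sz0 = NB6[k][0] + 1, sy0 = NB6[k][1] + 1, sx0 = NB6[k][2] + 1;
    if (nb[sz0][sy0][sx0] || seenb[sz0][sy0][sx0]) continue;
    ++nbg;
    if (nbg > 1) return false;
    std::vector<int> st;
    st.push_back(sz0 * 9 + sy0 * 3 + sx0);
    seenb[sz0][sy0][sx0] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cz = c / 9, cy = (c / 3) % 3, cx = c % 3;
      for (int k2 = 0; k2 < 6; ++k2) {
        int z2 = cz + NB6[k2][0], y2 = cy + NB6[k2][1], x2 = cx + NB6[k2][2];
        if (z2 < 0 || z2 > 2 || y2 < 0 || y2 > 2 || x2 < 0 || x2 > 2) continue;
        int manh = std::abs(z2 - 1) + std::abs(y2 - 1) + std::abs(x2 - 1);
        if (manh == 0 || manh > 2) continue; // stay inside N18
        if (!nb[z2][y2][x2] && !seenb[z2][y2][x2]) { seenb[z2][y2][x2] = true; st.push_back(z2 * 9 + y2 * 3 + x2); }
      }
    }
  }
  return nbg == 1;
}

// Sequential directional thinning: per iteration, six face-direction subpasses
// (z-,z+,y-,y+,x-,x+) delete, in raster order, border voxels that are simple and
// not curve endpoints (>=2 foreground 26-neighbors). Terminates at the medial curve.
// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector mask, IntegerVector dims) {
  Grid g(dims);
  std::vector<char> m(g.size());
  for (long i = 0; i < (long)g.size(); ++i) m[i] = mask[i] ? 1 : 0;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      int dz = NB6[d][0], dy = NB6[d][1], dx = NB6[d][2];
      // collect current border candidates for this direction, then delete sequentially
      std::vector<long> cand;
      for (int x = 0; x < g.nx; ++x) for (int y = 0; y < g.ny; ++y) for (int z = 0; z < g.nz; ++z) {
        long i = g.lin(z, y, x);
        if (!m[i]) continue;
        int z2 = z + dz, y2 = y + dy, x2 = x + dx;
        if (!g.in(z2, y2, x2) || !m[g.lin(z2, y2, x2)]) cand.push_back(i);
      }
      for (long i : cand) {
        if (!m[i]) continue;
        int z = i % g.nz, y = (i / g.nz) % g.ny, x = i / ((long)g.nz * g.ny);
        if (count_nb26(m, g, z, y, x) < 2) continue; // keep endpoints and isolated voxels
        if (is_simple(m, g, z, y, x)) { m[i] = 0; changed = true; }
      }
    }
  }
  LogicalVector out(mask.size());
  for (long i = 0; i < (long)g.size(); ++i) out[i] = m[i] != 0;
  return out;
}

// Foreground 26-neighbor counts (for skeleton graph construction).
// [[Rcpp::export]]
IntegerVector cpp_neighbor_counts(LogicalVector mask, IntegerVector dims) {
  Grid g(dims);
  std::vector<char> m(g.size());
  for (long i = 0; i < (long)g.size(); ++i) m[i] = mask[i] ? 1 : 0;
  IntegerVector out(mask.size(), 0);
  for (int x = 0; x < g.nx; ++x) for (int y = 0; y < g.ny; ++y) for (int z = 0; z < g.nz; ++z) {
    long i = g.lin(z, y, x);
    if (m[i]) out[i] = count_nb26(m, g, z, y, x);
  }
  return out;
}
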