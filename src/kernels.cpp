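#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Connected-component labelling of a 3D mask.
// connectivity: 6 (faces) or 26 (faces+edges+corners). Labels are 1..k in
// first-encounter order; non-mask voxels get 0.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  // Backward neighbour offsets (strictly smaller linear index).
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 0; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && (dy > 0 || (dy == 0 && dx >= 0))) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dx, dy, dz});
      }

  std::vector<int> parent(n);
  IntegerVector lab(n, 0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        parent[i] = (int)i;
        if (!mask[i]) continue;
        for (auto &o : offs) {
          int xx = x + o[0], yy = y + o[1], zz = z + o[2];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny) continue;
          R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
          if (mask[j]) uf_union(parent, (int)i, (int)j);
        }
      }

  int next = 0;
  std::vector<int> remap(n, 0);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int r = uf_find(parent, (int)i);
    if (remap[r] == 0) remap[r] = ++next;
    lab[i] = remap[r];
  }
  lab.attr("dim") = dims;
  return lab;
}

// 1D convolution of a 3D volume along one axis with edge replication.
// axis: 1=x (fastest), 2=y, 3=z. kernel length must be odd.
// [[Rcpp::export(name = ".convolve_axis")]]
NumericVector convolve_axis(NumericVector vol, IntegerVector dims,
                            NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int klen = kernel.size(), kr = klen / 2;
  if (klen % 2 == 0) stop("kernel length must be odd");
  NumericVector out(vol.size());
  out.attr("dim") = dims;
  const int nax = (axis == 1) ? nx : (axis == 2) ? ny : nz;

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        int pos = (axis == 1) ? x : (axis == 2) ? y : z;
        for (int k = -kr; k <= kr; ++k) {
          int p = pos + k;
          if (p < 0) p = 0;
          if (p >= nax) p = nax - 1;
          int xx = (axis == 1) ? p : x, yy = (axis == 2) ? p : y, zz = (axis == 3) ? p : z;
          acc += kernel[k + kr] * vol[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
        }
        out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = acc;
      }
  return out;
}

// Binary erosion/dilation with a Euclidean ball of given radius (voxels).
// op: 0 = erode, 1 = dilate. Outside the volume counts as background.
// [[Rcpp::export(name = ".morph_ball_3d")]]
LogicalVector morph_ball_3d(LogicalVector mask, IntegerVector dims,
                            double radius, int op) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int r = (int)std::floor(radius);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if (dx * dx + dy * dy + dz * dz <= radius * radius)
          offs.push_back({dx, dy, dz});

  LogicalVector out(mask.size());
  out.attr("dim") = dims;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        bool erode_ok = true, dilate_hit = false;
        for (auto &o : offs) {
          int xx = x + o[0], yy = y + o[1], zz = z + o[2];
          bool v = false;
          if (xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny && zz < nz)
            v = mask[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
          if (!v) erode_ok = false;
          if (v) dilate_hit = true;
          if (op == 0 && !erode_ok) break;
          if (op == 1 && dilate_hit) break;
        }
        out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = (op == 0) ? erode_ok : dilate_hit;
      }
  return out;
}
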