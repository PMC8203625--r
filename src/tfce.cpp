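#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// neighbour offsets for 6/18/26 connectivity on a 3-D grid
static std::vector<std::array<int, 3>> make_offsets(int connectivity) {
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        offs.push_back({dx, dy, dz});
      }
  return offs;
}

// BFS labelling of mask voxels; returns component id per voxel (0 = none)
// and fills sizes[component].
static void label_mask(const std::vector<char>& mask, int nx, int ny, int nz,
                       const std::vector<std::array<int, 3>>& offs,
                       std::vector<int>& lab, std::vector<int>& sizes) {
  const int V = nx * ny * nz;
  std::fill(lab.begin(), lab.end(), 0);
  sizes.clear();
  std::vector<int> stack;
  int next = 0;
  for (int v = 0; v < V; ++v) {
    if (!mask[v] || lab[v]) continue;
    ++next;
    int count = 0;
    stack.clear();
    stack.push_back(v);
    lab[v] = next;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      ++count;
      int x = cur % nx, y = (cur / nx) % ny, z = cur / (nx * ny);
      for (const auto& o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int nb = xx + nx * yy + nx * ny * zz;
        if (mask[nb] && !lab[nb]) {
          lab[nb] = next;
          stack.push_back(nb);
        }
      }
    }
    sizes.push_back(count);
  }
}

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int V = nx * ny * nz;
  std::vector<char> m(V);
  for (int i = 0; i < V; ++i) m[i] = mask[i] == TRUE;
  std::vector<int> lab(V), sizes;
  auto offs = make_offsets(connectivity);
  label_mask(m, nx, ny, nz, offs, lab, sizes);
  IntegerVector out(V);
  for (int i = 0; i < V; ++i) out[i] = lab[i];
  out.attr("dim") = dims;
  return out;
}

// Threshold-free cluster enhancement of a non-negative statistic map:
// TFCE(v) = sum over thresholds h of e(v,h)^E * h^H * dh, where e(v,h) is
// the extent of the connected supra-threshold component containing v.
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector map, IntegerVector dims,
                       double E, double H, double dh, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int V = nx * ny * nz;
  NumericVector out(V);
  double mx = 0.0;
  for (int i = 0; i < V; ++i) {
    if (map[i] < 0) stop("tfce_cpp expects a non-negative map");
    if (map[i] > mx) mx = map[i];
  }
  if (mx <= 0.0 || dh <= 0.0) {
    out.attr("dim") = dims;
    return out;
  }
  auto offs = make_offsets(connectivity);
  std::vector<char> mask(V);
  std::vector<int> lab(V), sizes;
  for (double h = dh; h <= mx + 1e-12; h += dh) {
    for (int i = 0; i < V; ++i) mask[i] = map[i] >= h;
    label_mask(mask, nx, ny, nz, offs, lab, sizes);
    double hh = std::pow(h, H) * dh;
    for (int i = 0; i < V; ++i)
      if (lab[i]) out[i] += std::pow((double)sizes[lab[i] - 1], E) * hh;
  }
  out.attr("dim") = dims;
  return out;
}
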