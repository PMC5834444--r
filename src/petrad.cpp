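// Low-level voxel routines: connected-component labelling and the
// marker-based watershed flood. Both operate on 3-D arrays passed as flat
// vectors in R's column-major layout.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static inline int64_t lin(int x, int y, int z, int nx, int ny) {
  return (int64_t)x + (int64_t)nx * ((int64_t)y + (int64_t)ny * z);
}

// neighbour offsets for 6- or 26-connectivity
static void neighbour_offsets(int connectivity,
                              std::vector<std::array<int, 3> > &off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m != 1) continue;
        off.push_back({dx, dy, dz});
      }
}

// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dims,
                       int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = (int64_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int, 3> > off;
  neighbour_offsets(connectivity, off);
  std::vector<int64_t> stack;
  int next = 0;
  for (int64_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      int64_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((int64_t)nx * ny));
      for (size_t k = 0; k < off.size(); ++k) {
        int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        int64_t u = lin(xx, yy, zz, nx, ny);
        if (mask[u] && lab[u] == 0) {
          lab[u] = next;
          stack.push_back(u);
        }
      }
    }
  }
  lab.attr("max_label") = next;
  return lab;
}

struct FloodNode {
  double value;   // smoothed SUV at the voxel
  int64_t index;  // linear index, used for deterministic tie-breaks
};

// Highest SUV first; ties broken towards the smaller linear index.
struct FloodOrder {
  bool operator()(const FloodNode &a, const FloodNode &b) const {
    if (a.value != b.value) return a.value < b.value;
    return a.index > b.index;
  }
};

// Marker-based watershed flood, 6-connected, on the (negated) smoothed SUV
// landscape: unassigned mask voxels adjacent to assigned ones are claimed in
// order of descending SUV; each claimed voxel takes the label of its
// assigned 6-neighbour with the highest SUV (ties towards the smaller
// linear index). Marker voxels carry their labels from the start.
// [[Rcpp::export(name = ".watershed_flood")]]
IntegerVector watershed_flood(NumericVector suv, LogicalVector mask,
                              IntegerVector markers, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = (int64_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::priority_queue<FloodNode, std::vector<FloodNode>, FloodOrder> heap;

  for (int64_t v = 0; v < n; ++v)
    if (markers[v] > 0) lab[v] = markers[v];

  const int dxs[6] = {-1, 1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, -1, 1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, -1, 1};

  // seed the frontier: unassigned mask voxels 6-adjacent to a marker
  for (int64_t v = 0; v < n; ++v) {
    if (lab[v] == 0) continue;
    int x = (int)(v % nx);
    int y = (int)((v / nx) % ny);
    int z = (int)(v / ((int64_t)nx * ny));
    for (int k = 0; k < 6; ++k) {
      int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      int64_t u = lin(xx, yy, zz, nx, ny);
      if (mask[u] && lab[u] == 0) heap.push({suv[u], u});
    }
  }

  while (!heap.empty()) {
    FloodNode node = heap.top();
    heap.pop();
    int64_t v = node.index;
    if (lab[v] != 0) continue;  // stale duplicate
    int x = (int)(v % nx);
    int y = (int)((v / nx) % ny);
    int z = (int)(v / ((int64_t)nx * ny));
    // label of the assigned 6-neighbour with the highest SUV
    int best = 0;
    double best_suv = -1.0;
    int64_t best_idx = -1;
    for (int k = 0; k < 6; ++k) {
      int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      int64_t u = lin(xx, yy, zz, nx, ny);
      if (lab[u] > 0) {
        if (suv[u] > best_suv || (suv[u] == best_suv && u < best_idx)) {
          best = lab[u];
          best_suv = suv[u];
          best_idx = u;
        }
      }
    }
    lab[v] = best;
    for (int k = 0; k < 6; ++k) {
      int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      int64_t u = lin(xx, yy, zz, nx, ny);
      if (mask[u] && lab[u] == 0) heap.push({suv[u], u});
    }
  }
  return lab;
}

// Exact maximum pairwise Euclidean distance among a candidate point set
// (rows of a 3-column matrix, already pruned in R).
// [[Rcpp::export(name = ".max_pair_dist")]]
double max_pair_dist(NumericMatrix pts) {
  const int n = pts.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double dz = pts(i, 2) - pts(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d > best) best = d;
    }
  return std::sqrt(best);
}
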