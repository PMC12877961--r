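// Voxel-graph primitives: 3D connected-component labeling, intensity-weighted
// Dijkstra tracing, geodesic spanning trees and tip detection.
//
// Conventions shared with the R layer:
//  - grids are R arrays dim = (nz, ny, nx), column-major, z fastest;
//    0-based linear index L = (x*ny + y)*nz + z
//  - spacing is (dz, dy, dx) in micrometres; edge weights are physical step
//    length times the mean of the endpoint cost values
//  - deterministic tie-breaking everywhere by lexicographic (z, y, x)

#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

struct Dim {
  int nz, ny, nx;
};

static inline Dim as_dim(const IntegerVector& dim) {
  Dim d;
  d.nz = dim[0]; d.ny = dim[1]; d.nx = dim[2];
  return d;
}

static inline void lin2zyx(int lin, const Dim& d, int& z, int& y, int& x) {
  z = lin % d.nz;
  int r = lin / d.nz;
  y = r % d.ny;
  x = r / d.ny;
}

static inline int zyx2lin(int z, int y, int x, const Dim& d) {
  return (x * d.ny + y) * d.nz + z;
}

// lexicographic (z, y, x) rank used for all tie-breaking
static inline int64_t tiekey(int z, int y, int x, const Dim& d) {
  return ((int64_t)z * d.ny + y) * d.nx + x;
}

struct Offsets {
  std::vector<int> dz, dy, dx;
  std::vector<double> step;  // physical step length, filled when spacing known
};

// connectivity 6: face, 18: face+edge, 26: face+edge+corner
static Offsets make_offsets(int connectivity, const double* sp /* may be NULL */) {
  Offsets o;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int nn = std::abs(a) + std::abs(b) + std::abs(c);
        if (nn == 0) continue;
        if (connectivity == 6 && nn > 1) continue;
        if (connectivity == 18 && nn > 2) continue;
        o.dz.push_back(a); o.dy.push_back(b); o.dx.push_back(c);
        if (sp) {
          double s = std::sqrt(a * a * sp[0] * sp[0] + b * b * sp[1] * sp[1] +
                               c * c * sp[2] * sp[2]);
          o.step.push_back(s);
        }
      }
  return o;
}

// [[Rcpp::export]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  Dim d = as_dim(dim);
  const int n = mask.size();
  IntegerVector labels(n, 0);
  Offsets off = make_offsets(connectivity, NULL);
  std::vector<int> stack;
  int next = 0;
  for (int seed = 0; seed < n; ++seed) {
    if (!mask[seed] || labels[seed] != 0) continue;
    ++next;
    labels[seed] = next;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int z, y, x;
      lin2zyx(cur, d, z, y, x);
      for (size_t k = 0; k < off.dz.size(); ++k) {
        int zz = z + off.dz[k], yy = y + off.dy[k], xx = x + off.dx[k];
        if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx)
          continue;
        int nb = zyx2lin(zz, yy, xx, d);
        if (mask[nb] && labels[nb] == 0) {
          labels[nb] = next;
          stack.push_back(nb);
        }
      }
    }
  }
  labels.attr("n_labels") = next;
  return labels;
}

struct HeapNode {
  double cost;
  int64_t tie;
  int idx;
};
struct HeapCmp {
  bool operator()(const HeapNode& a, const HeapNode& b) const {
    if (a.cost != b.cost) return a.cost > b.cost;
    return a.tie > b.tie;
  }
};

// Shortest intensity-weighted path on the 26-neighbor voxel graph.
// goal: logical vector marking acceptable goal voxels; the search stops at the
// first goal settled. goal_ref (0-based linear, or -1) is only used to report
// the most promising frontier voxel when the cost cap aborts the search.
// [[Rcpp::export]]
List dijkstra_voxel(NumericVector cost, IntegerVector dim, NumericVector spacing,
                    int start, LogicalVector goal, int goal_ref, double cost_cap) {
  Dim d = as_dim(dim);
  const int n = cost.size();
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  Offsets off = make_offsets(26, sp);

  std::vector<double> dist(n, R_PosInf);
  std::vector<int> parent(n, -1);
  std::vector<char> settled(n, 0);
  std::priority_queue<HeapNode, std::vector<HeapNode>, HeapCmp> heap;
  int sz, sy, sx;
  lin2zyx(start, d, sz, sy, sx);
  dist[start] = 0.0;
  heap.push({0.0, tiekey(sz, sy, sx, d), start});

  // physical coordinates of the reference goal, for frontier reporting
  double gx = 0, gy = 0, gz = 0;
  bool have_ref = goal_ref >= 0;
  if (have_ref) {
    int z, y, x;
    lin2zyx(goal_ref, d, z, y, x);
    gz = z * sp[0]; gy = y * sp[1]; gx = x * sp[2];
  }
  int best_frontier = start;
  double best_h = R_PosInf;

  int reached = -1;
  while (!heap.empty()) {
    HeapNode top = heap.top();
    heap.pop();
    int cur = top.idx;
    if (settled[cur]) continue;
    settled[cur] = 1;
    if (top.cost > cost_cap) break;
    int z, y, x;
    lin2zyx(cur, d, z, y, x);
    if (have_ref) {
      double hz = z * sp[0] - gz, hy = y * sp[1] - gy, hx = x * sp[2] - gx;
      double h = std::sqrt(hz * hz + hy * hy + hx * hx);
      if (h < best_h) { best_h = h; best_frontier = cur; }
    } else {
      best_frontier = cur;
    }
    if (goal[cur]) { reached = cur; break; }
    for (size_t k = 0; k < off.dz.size(); ++k) {
      int zz = z + off.dz[k], yy = y + off.dy[k], xx = x + off.dx[k];
      if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx)
        continue;
      int nb = zyx2lin(zz, yy, xx, d);
      if (settled[nb]) continue;
      double w = off.step[k] * 0.5 * (cost[cur] + cost[nb]);
      double nc = top.cost + w;
      if (nc < dist[nb]) {
        dist[nb] = nc;
        parent[nb] = cur;
        heap.push({nc, tiekey(zz, yy, xx, d), nb});
      } else if (nc == dist[nb] && parent[nb] >= 0) {
        // equal-cost relaxation: prefer the lexicographically smaller parent
        int pz, py, px;
        lin2zyx(parent[nb], d, pz, py, px);
        if (tiekey(z, y, x, d) < tiekey(pz, py, px, d))
          parent[nb] = cur;
      }
    }
  }

  List out;
  if (reached >= 0) {
    std::vector<int> path;
    for (int v = reached; v >= 0; v = parent[v]) path.push_back(v);
    std::reverse(path.begin(), path.end());
    out = List::create(_["reached"] = true,
                       _["path"] = IntegerVector(path.begin(), path.end()),
                       _["cost"] = dist[reached],
                       _["frontier"] = reached);
  } else {
    out = List::create(_["reached"] = false,
                       _["path"] = IntegerVector(0),
                       _["cost"] = NA_REAL,
                       _["frontier"] = best_frontier);
  }
  return out;
}

// Full single-source geodesic distance + shortest-path tree restricted to a
// mask (used to skeletonize a segmented neuron).
// [[Rcpp::export]]
List geodesic_tree_cpp(NumericVector cost, LogicalVector mask, IntegerVector dim,
                       NumericVector spacing, int root) {
  Dim d = as_dim(dim);
  const int n = cost.size();
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  Offsets off = make_offsets(26, sp);

  NumericVector dist(n, R_PosInf);
  IntegerVector parent(n, -1L);
  std::vector<char> settled(n, 0);
  std::priority_queue<HeapNode, std::vector<HeapNode>, HeapCmp> heap;

  int rz, ry, rx;
  lin2zyx(root, d, rz, ry, rx);
  dist[root] = 0.0;
  heap.push({0.0, tiekey(rz, ry, rx, d), root});

  while (!heap.empty()) {
    HeapNode top = heap.top();
    heap.pop();
    int cur = top.idx;
    if (settled[cur]) continue;
    settled[cur] = 1;
    int z, y, x;
    lin2zyx(cur, d, z, y, x);
    for (size_t k = 0; k < off.dz.size(); ++k) {
      int zz = z + off.dz[k], yy = y + off.dy[k], xx = x + off.dx[k];
      if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx)
        continue;
      int nb = zyx2lin(zz, yy, xx, d);
      if (!mask[nb] || settled[nb]) continue;
      double w = off.step[k] * 0.5 * (cost[cur] + cost[nb]);
      double nc = top.cost + w;
      if (nc < dist[nb]) {
        dist[nb] = nc;
        parent[nb] = cur;
        heap.push({nc, tiekey(zz, yy, xx, d), nb});
      } else if (nc == dist[nb] && parent[nb] >= 0) {
        int pz, py, px;
        lin2zyx(parent[nb], d, pz, py, px);
        if (tiekey(z, y, x, d) < tiekey(pz, py, px, d)) parent[nb] = cur;
      }
    }
  }
  return List::create(_["dist"] = dist, _["parent"] = parent);
}

// Geodesic-distance local maxima within the mask under 26-adjacency.
// Plateaus are broken by the lexicographic (z, y, x) order so each flat apex
// yields a single representative tip.
// [[Rcpp::export]]
IntegerVector geodesic_tips_cpp(NumericVector dist, LogicalVector mask,
                                IntegerVector dim) {
  Dim d = as_dim(dim);
  const int n = dist.size();
  Offsets off = make_offsets(26, NULL);
  std::vector<int> tips;
  for (int cur = 0; cur < n; ++cur) {
    if (!mask[cur] || !R_FINITE(dist[cur])) continue;
    int z, y, x;
    lin2zyx(cur, d, z, y, x);
    int64_t mytie = tiekey(z, y, x, d);
    bool is_tip = true;
    for (size_t k = 0; k < off.dz.size() && is_tip; ++k) {
      int zz = z + off.dz[k], yy = y + off.dy[k], xx = x + off.dx[k];
      if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx)
        continue;
      int nb = zyx2lin(zz, yy, xx, d);
      if (!mask[nb] || !R_FINITE(dist[nb])) continue;
      if (dist[nb] > dist[cur]) is_tip = false;
      else if (dist[nb] == dist[cur] && tiekey(zz, yy, xx, d) < mytie)
        is_tip = false;
    }
    if (is_tip) tips.push_back(cur);
  }
  return IntegerVector(tips.begin(), tips.end());
}

// Two-pass 26-neighbor chamfer distance transform (physical um) of a mask:
// distance from each mask voxel to the nearest background voxel. Used to
// canalize skeleton geodesics onto the tube core.
// [[Rcpp::export]]
NumericVector chamfer_dt_cpp(LogicalVector mask, IntegerVector dim,
                             NumericVector spacing) {
  Dim d = as_dim(dim);
  const int n = mask.size();
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  Offsets off = make_offsets(26, sp);
  const double big = 1e30;
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) dist[i] = mask[i] ? big : 0.0;
  // boundary seed: mask voxels start at half the step to their nearest
  // background neighbor, handled implicitly by relaxing from background 0
  for (int pass = 0; pass < 2; ++pass) {
    bool forward = pass == 0;
    for (int ii = 0; ii < n; ++ii) {
      int cur = forward ? ii : (n - 1 - ii);
      if (!mask[cur]) continue;
      int z, y, x;
      lin2zyx(cur, d, z, y, x);
      for (size_t k = 0; k < off.dz.size(); ++k) {
        int zz = z + off.dz[k], yy = y + off.dy[k], xx = x + off.dx[k];
        double nb_dist;
        if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny || xx < 0 ||
            xx >= d.nx)
          nb_dist = 0.0;  // outside the grid counts as background
        else
          nb_dist = dist[zyx2lin(zz, yy, xx, d)];
        double cand = nb_dist + off.step[k];
        if (cand < dist[cur]) dist[cur] = cand;
      }
    }
  }
  return dist;
}
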