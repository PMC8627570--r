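#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Zhang-Suen two-subiteration thinning of a 0/1 mask. Returns the one-pixel
// wide skeleton. Connectivity of the input component is preserved.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img(clone(mask));
  std::vector<std::pair<int,int> > del;
  del.reserve(256);
  bool changed = true;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      del.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!img(r, c)) continue;
          int p2 = (r > 0)              ? img(r-1, c)   : 0;
          int p3 = (r > 0 && c < nc-1)  ? img(r-1, c+1) : 0;
          int p4 = (c < nc-1)           ? img(r,   c+1) : 0;
          int p5 = (r < nr-1 && c < nc-1) ? img(r+1, c+1) : 0;
          int p6 = (r < nr-1)           ? img(r+1, c)   : 0;
          int p7 = (r < nr-1 && c > 0)  ? img(r+1, c-1) : 0;
          int p8 = (c > 0)              ? img(r,   c-1) : 0;
          int p9 = (r > 0 && c > 0)     ? img(r-1, c-1) : 0;
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(std::make_pair(r, c));
        }
      }
      if (!del.empty()) changed = true;
      for (size_t i = 0; i < del.size(); ++i)
        img(del[i].first, del[i].second) = 0;
    }
  }
  return img;
}

static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1,  0,  1, -1, 1, -1, 0, 1};

// BFS over the 8-connected skeleton from `start`; fills hop distances and
// parents, returns the farthest reachable pixel.
static int bfs_far(const std::vector<char> &on, int nr, int nc, int start,
                   std::vector<int> &dist, std::vector<int> &parent) {
  std::fill(dist.begin(), dist.end(), -1);
  std::fill(parent.begin(), parent.end(), -1);
  std::queue<int> q;
  dist[start] = 0;
  q.push(start);
  int far = start;
  while (!q.empty()) {
    int v = q.front(); q.pop();
    int r = v % nr, c = v / nr;
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int u = rr + cc * nr;
      if (!on[u] || dist[u] >= 0) continue;
      dist[u] = dist[v] + 1;
      parent[u] = v;
      q.push(u);
      if (dist[u] > dist[far]) far = u;
    }
  }
  return far;
}

// Skeletonize a mask and extract its longest geodesic path (the body axis):
// double-sweep BFS from an arbitrary skeleton pixel. Returns the ordered
// path as 1-based (row, col) plus the total skeleton pixel count, so the
// caller can reject masks whose axis covers too little of the skeleton
// (branched or non-elongated objects).
// [[Rcpp::export]]
List cpp_skeleton_path(IntegerMatrix mask) {
  IntegerMatrix skel = cpp_thin(mask);
  int nr = skel.nrow(), nc = skel.ncol();
  std::vector<char> on((size_t)nr * nc, 0);
  int n_skel = 0, first = -1;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (skel(r, c)) {
        on[r + (size_t)c * nr] = 1;
        ++n_skel;
        if (first < 0) first = r + c * nr;
      }
  if (n_skel < 2)
    return List::create(_["path"] = IntegerMatrix(0, 2),
                        _["n_skeleton"] = n_skel);
  std::vector<int> dist((size_t)nr * nc), parent((size_t)nr * nc);
  int a = bfs_far(on, nr, nc, first, dist, parent);
  int b = bfs_far(on, nr, nc, a, dist, parent);
  std::vector<int> path;
  for (int v = b; v >= 0; v = parent[v]) path.push_back(v);
  int k = (int)path.size();
  IntegerMatrix out(k, 2);
  for (int i = 0; i < k; ++i) {
    out(i, 0) = path[k - 1 - i] % nr + 1;  // row
    out(i, 1) = path[k - 1 - i] / nr + 1;  // col
  }
  return List::create(_["path"] = out, _["n_skeleton"] = n_skel);
}

// Rasterize a body silhouette as the union of disks centered on a finely
// sampled midline: (x, y) are 1-based pixel coordinates (col, row), rad the
// local half-width in pixels. The nearest pixel to each center is always
// set, so zero-width tapered tips stay connected.
// [[Rcpp::export]]
IntegerMatrix cpp_render_frame(NumericVector x, NumericVector y,
                               NumericVector rad, int nrow, int ncol) {
  IntegerMatrix img(nrow, ncol);
  int n = x.size();
  for (int i = 0; i < n; ++i) {
    double cx = x[i], cy = y[i], r = rad[i];
    int rc = (int)std::lround(cy) - 1, cc = (int)std::lround(cx) - 1;
    if (rc >= 0 && rc < nrow && cc >= 0 && cc < ncol) img(rc, cc) = 1;
    if (r <= 0.5) continue;
    int r0 = std::max(0, (int)std::floor(cy - r) - 1);
    int r1 = std::min(nrow - 1, (int)std::ceil(cy + r) - 1);
    int c0 = std::max(0, (int)std::floor(cx - r) - 1);
    int c1 = std::min(ncol - 1, (int)std::ceil(cx + r) - 1);
    double r2 = r * r;
    for (int c = c0; c <= c1; ++c) {
      double dx = (c + 1) - cx;
      for (int rr = r0; rr <= r1; ++rr) {
        double dy = (rr + 1) - cy;
        if (dx * dx + dy * dy <= r2) img(rr, c) = 1;
      }
    }
  }
  return img;
}
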