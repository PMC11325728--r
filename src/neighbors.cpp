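#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Minimal 3D kd-tree over the rows of an N x 3 coordinate matrix.
// Build is O(N log N) (median split via nth_element); queries are the
// standard branch-and-bound descent.
namespace {

struct KdTree {
  const double *x, *y, *z;
  int n;
  std::vector<int> idx;    // permutation of 0..n-1, tree stored implicitly
  std::vector<int> axis;   // split axis per tree node (aligned with idx order)

  double coord(int i, int ax) const {
    return ax == 0 ? x[i] : (ax == 1 ? y[i] : z[i]);
  }

  void build(const double *px, const double *py, const double *pz, int nn) {
    x = px; y = py; z = pz; n = nn;
    idx.resize(n);
    axis.assign(n, 0);
    for (int i = 0; i < n; ++i) idx[i] = i;
    if (n > 0) build_rec(0, n);
  }

  void build_rec(int lo, int hi) {
    if (hi - lo <= 1) return;
    // split along the axis of largest spread
    double mn[3] = {R_PosInf, R_PosInf, R_PosInf};
    double mx[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = lo; i < hi; ++i) {
      for (int a = 0; a < 3; ++a) {
        double v = coord(idx[i], a);
        if (v < mn[a]) mn[a] = v;
        if (v > mx[a]) mx[a] = v;
      }
    }
    int ax = 0;
    double best = mx[0] - mn[0];
    for (int a = 1; a < 3; ++a)
      if (mx[a] - mn[a] > best) { best = mx[a] - mn[a]; ax = a; }
    int mid = lo + (hi - lo) / 2;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) { return coord(a, ax) < coord(b, ax); });
    axis[mid] = ax;
    build_rec(lo, mid);
    build_rec(mid + 1, hi);
  }

  // single nearest neighbor, optionally excluding a given index (for self-queries)
  void nn1(double qx, double qy, double qz, int exclude,
           int &best_i, double &best_d2) const {
    best_i = -1;
    best_d2 = R_PosInf;
    nn1_rec(0, n, qx, qy, qz, exclude, best_i, best_d2);
  }

  void nn1_rec(int lo, int hi, double qx, double qy, double qz, int exclude,
               int &best_i, double &best_d2) const {
    if (hi <= lo) return;
    int mid = lo + (hi - lo) / 2;
    int i = idx[mid];
    if (i != exclude) {
      double dx = x[i] - qx, dy = y[i] - qy, dz = z[i] - qz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best_d2) { best_d2 = d2; best_i = i; }
    }
    if (hi - lo == 1) return;
    int ax = axis[mid];
    double q = ax == 0 ? qx : (ax == 1 ? qy : qz);
    double split = coord(i, ax);
    double diff = q - split;
    if (diff < 0) {
      nn1_rec(lo, mid, qx, qy, qz, exclude, best_i, best_d2);
      if (diff * diff < best_d2)
        nn1_rec(mid + 1, hi, qx, qy, qz, exclude, best_i, best_d2);
    } else {
      nn1_rec(mid + 1, hi, qx, qy, qz, exclude, best_i, best_d2);
      if (diff * diff < best_d2)
        nn1_rec(lo, mid, qx, qy, qz, exclude, best_i, best_d2);
    }
  }

  // k nearest neighbors (excluding the query's own index when exclude >= 0)
  void knn(double qx, double qy, double qz, int k, int exclude,
           std::priority_queue<std::pair<double, int> > &heap) const {
    knn_rec(0, n, qx, qy, qz, k, exclude, heap);
  }

  void knn_rec(int lo, int hi, double qx, double qy, double qz, int k,
               int exclude, std::priority_queue<std::pair<double, int> > &heap) const {
    if (hi <= lo) return;
    int mid = lo + (hi - lo) / 2;
    int i = idx[mid];
    if (i != exclude) {
      double dx = x[i] - qx, dy = y[i] - qy, dz = z[i] - qz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if ((int)heap.size() < k) heap.push(std::make_pair(d2, i));
      else if (d2 < heap.top().first) { heap.pop(); heap.push(std::make_pair(d2, i)); }
    }
    if (hi - lo == 1) return;
    int ax = axis[mid];
    double q = ax == 0 ? qx : (ax == 1 ? qy : qz);
    double diff = q - coord(i, ax);
    double bound = ((int)heap.size() < k) ? R_PosInf : heap.top().first;
    if (diff < 0) {
      knn_rec(lo, mid, qx, qy, qz, k, exclude, heap);
      bound = ((int)heap.size() < k) ? R_PosInf : heap.top().first;
      if (diff * diff < bound) knn_rec(mid + 1, hi, qx, qy, qz, k, exclude, heap);
    } else {
      knn_rec(mid + 1, hi, qx, qy, qz, k, exclude, heap);
      bound = ((int)heap.size() < k) ? R_PosInf : heap.top().first;
      if (diff * diff < bound) knn_rec(lo, mid, qx, qy, qz, k, exclude, heap);
    }
  }
};

}  // namespace

// Nearest neighbor in `target` for every row of `query`.
// Returns 1-based indices and Euclidean distances.
// [[Rcpp::export]]
List cpp_nn1(NumericMatrix query, NumericMatrix target) {
  int nq = query.nrow(), nt = target.nrow();
  if (nt == 0) stop("empty target cloud");
  std::vector<double> tx(nt), ty(nt), tz(nt);
  for (int i = 0; i < nt; ++i) { tx[i] = target(i, 0); ty[i] = target(i, 1); tz[i] = target(i, 2); }
  KdTree tree;
  tree.build(tx.data(), ty.data(), tz.data(), nt);
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    int bi; double bd2;
    tree.nn1(query(i, 0), query(i, 1), query(i, 2), -1, bi, bd2);
    idx[i] = bi + 1;
    dist[i] = std::sqrt(bd2);
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Mean distance to the k nearest neighbors of each point within the same
// cloud (self excluded) -- the statistic behind the SOR filter.
// [[Rcpp::export]]
NumericVector cpp_knn_mean_dist(NumericMatrix pts, int k) {
  int n = pts.nrow();
  if (k < 1) stop("k must be >= 1");
  if (n <= k) stop("need more points than neighbors");
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pts(i, 0); y[i] = pts(i, 1); z[i] = pts(i, 2); }
  KdTree tree;
  tree.build(x.data(), y.data(), z.data(), n);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::priority_queue<std::pair<double, int> > heap;
    tree.knn(x[i], y[i], z[i], k, i, heap);
    double s = 0.0;
    while (!heap.empty()) { s += std::sqrt(heap.top().first); heap.pop(); }
    out[i] = s / k;
  }
  return out;
}

// Greedy min-distance thinning in input order using a uniform grid hash with
// cell size d: a point is kept iff no previously kept point lies within d.
// [[Rcpp::export]]
LogicalVector cpp_min_dist_subsample(NumericMatrix pts, double d) {
  int n = pts.nrow();
  if (d <= 0) stop("d must be > 0");
  LogicalVector keep(n);
  if (n == 0) return keep;
  double d2 = d * d;
  const double inv = 1.0 / d;
  typedef long long key_t_;
  std::unordered_map<key_t_, std::vector<int> > grid;
  grid.reserve(2 * (size_t)n);
  auto cell_key = [&](long long cx, long long cy, long long cz) -> key_t_ {
    // pack three 21-bit signed cell coordinates
    const long long off = 1LL << 20;
    return ((cx + off) << 42) | ((cy + off) << 21) | (cz + off);
  };
  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    long long cx = (long long)std::floor(px * inv);
    long long cy = (long long)std::floor(py * inv);
    long long cz = (long long)std::floor(pz * inv);
    bool ok = true;
    for (long long ax = cx - 1; ax <= cx + 1 && ok; ++ax)
      for (long long ay = cy - 1; ay <= cy + 1 && ok; ++ay)
        for (long long az = cz - 1; az <= cz + 1 && ok; ++az) {
          auto it = grid.find(cell_key(ax, ay, az));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            double dx = pts(j, 0) - px, dy = pts(j, 1) - py, dz = pts(j, 2) - pz;
            if (dx * dx + dy * dy + dz * dz < d2) { ok = false; break; }
          }
        }
    keep[i] = ok;
    if (ok) grid[cell_key(cx, cy, cz)].push_back(i);
  }
  return keep;
}

// k nearest neighbors in `target` for each row of `query`; returns 1-based
// index and distance matrices with columns ordered nearest-first.
// [[Rcpp::export]]
List cpp_knn(NumericMatrix query, NumericMatrix target, int k) {
  int nq = query.nrow(), nt = target.nrow();
  if (nt == 0) stop("empty target cloud");
  if (k < 1 || k > nt) stop("invalid k");
  std::vector<double> tx(nt), ty(nt), tz(nt);
  for (int i = 0; i < nt; ++i) { tx[i] = target(i, 0); ty[i] = target(i, 1); tz[i] = target(i, 2); }
  KdTree tree;
  tree.build(tx.data(), ty.data(), tz.data(), nt);
  IntegerMatrix idx(nq, k);
  NumericMatrix dist(nq, k);
  for (int i = 0; i < nq; ++i) {
    std::priority_queue<std::pair<double, int> > heap;
    tree.knn(query(i, 0), query(i, 1), query(i, 2), k, -1, heap);
    int pos = (int)heap.size() - 1;
    while (!heap.empty()) {
      idx(i, pos) = heap.top().second + 1;
      dist(i, pos) = std::sqrt(heap.top().first);
      heap.pop();
      --pos;
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}
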