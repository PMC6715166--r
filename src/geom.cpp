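#include <Rcpp.h>
#include <unordered_map>
#include <functional>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---- exact nearest-neighbour distances -------------------------------------
// For each row of A, the minimum Euclidean distance to any row of B.
// Exact (not approximate): sweep over B sorted along its widest axis and
// prune with the 1-D gap, which is near-linear for surface point clouds.
// [[Rcpp::export]]
NumericVector cpp_nn_min_dist(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  if (m == 0) stop("reference cloud is empty");
  // pick axis with largest range in B
  int ax = 0; double best_range = -1.0;
  for (int k = 0; k < 3; ++k) {
    double lo = B(0, k), hi = B(0, k);
    for (int i = 1; i < m; ++i) { double v = B(i, k); if (v < lo) lo = v; if (v > hi) hi = v; }
    if (hi - lo > best_range) { best_range = hi - lo; ax = k; }
  }
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) { return B(a, ax) < B(b, ax); });
  std::vector<double> key(m);
  for (int i = 0; i < m; ++i) key[i] = B(ord[i], ax);

  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double qx = A(i, 0), qy = A(i, 1), qz = A(i, 2);
    const double qk = (ax == 0 ? qx : (ax == 1 ? qy : qz));
    int pos = int(std::lower_bound(key.begin(), key.end(), qk) - key.begin());
    double best = R_PosInf;
    int lo = pos - 1, hi = pos;
    while (lo >= 0 || hi < m) {
      bool take_hi;
      if (lo < 0) take_hi = true;
      else if (hi >= m) take_hi = false;
      else take_hi = (key[hi] - qk) <= (qk - key[lo]);
      int j; double gap;
      if (take_hi) { j = ord[hi]; gap = key[hi] - qk; ++hi; }
      else         { j = ord[lo]; gap = qk - key[lo]; --lo; }
      if (gap * gap > best) break;  // no closer point possible along sweep
      const double dx = B(j, 0) - qx, dy = B(j, 1) - qy, dz = B(j, 2) - qz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---- strict Poisson-disk sampling on a triangle mesh -----------------------
// Dart throwing with a uniform hash grid; the exclusion radius is relaxed
// geometrically until exactly n points are accepted. Uses R's RNG so the
// result is reproducible under set.seed().
struct CellKey {
  long long x, y, z;
  bool operator==(const CellKey& o) const { return x == o.x && y == o.y && z == o.z; }
};
struct CellHash {
  size_t operator()(const CellKey& k) const {
    return std::hash<long long>()(k.x * 73856093LL ^ k.y * 19349663LL ^ k.z * 83492791LL);
  }
};

// [[Rcpp::export]]
List cpp_poisson_disk(NumericMatrix V, IntegerMatrix F, NumericVector cumarea,
                      int n, double r0, double relax, int attempts_per_round) {
  const int nf = F.nrow();
  if (nf == 0) stop("mesh has no faces");
  double total = cumarea[nf - 1];
  if (!(total > 0)) stop("mesh has zero surface area");
  double r = r0;
  std::vector<double> px, py, pz;
  std::vector<int> src;
  px.reserve(n); py.reserve(n); pz.reserve(n); src.reserve(n);
  std::unordered_map<CellKey, std::vector<int>, CellHash> grid;
  double cell = r;  // grid rebuilt on relaxation
  int guard = 0;
  while ((int)px.size() < n) {
    int accepted_this_round = 0;
    for (int att = 0; att < attempts_per_round && (int)px.size() < n; ++att) {
      // area-weighted triangle, uniform barycentric point
      double u = unif_rand() * total;
      int t = int(std::lower_bound(cumarea.begin(), cumarea.end(), u) - cumarea.begin());
      if (t >= nf) t = nf - 1;
      double a = unif_rand(), b = unif_rand();
      if (a + b > 1.0) { a = 1.0 - a; b = 1.0 - b; }
      const int i0 = F(t, 0), i1 = F(t, 1), i2 = F(t, 2);
      const double x = V(i0,0) + a * (V(i1,0) - V(i0,0)) + b * (V(i2,0) - V(i0,0));
      const double y = V(i0,1) + a * (V(i1,1) - V(i0,1)) + b * (V(i2,1) - V(i0,1));
      const double z = V(i0,2) + a * (V(i1,2) - V(i0,2)) + b * (V(i2,2) - V(i0,2));
      CellKey c{ (long long)std::floor(x / cell), (long long)std::floor(y / cell),
                 (long long)std::floor(z / cell) };
      bool ok = true;
      for (long long dx = -1; dx <= 1 && ok; ++dx)
        for (long long dy = -1; dy <= 1 && ok; ++dy)
          for (long long dz = -1; dz <= 1 && ok; ++dz) {
            auto it = grid.find(CellKey{ c.x + dx, c.y + dy, c.z + dz });
            if (it == grid.end()) continue;
            for (int j : it->second) {
              const double ddx = px[j] - x, ddy = py[j] - y, ddz = pz[j] - z;
              if (ddx * ddx + ddy * ddy + ddz * ddz < r * r) { ok = false; break; }
            }
          }
      if (ok) {
        px.push_back(x); py.push_back(y); pz.push_back(z); src.push_back(t + 1);
        grid[c].push_back((int)px.size() - 1);
        ++accepted_this_round;
      }
    }
    if ((int)px.size() >= n) break;
    // strict packing unreachable at this radius: relax and rebuild the grid
    r *= relax;
    cell = r;
    grid.clear();
    for (int j = 0; j < (int)px.size(); ++j) {
      CellKey c{ (long long)std::floor(px[j] / cell), (long long)std::floor(py[j] / cell),
                 (long long)std::floor(pz[j] / cell) };
      grid[c].push_back(j);
    }
    if (++guard > 200) stop("Poisson-disk sampling failed to place requested points");
    (void)accepted_this_round;
  }
  NumericMatrix P(n, 3);
  IntegerVector S(n);
  for (int i = 0; i < n; ++i) { P(i,0) = px[i]; P(i,1) = py[i]; P(i,2) = pz[i]; S[i] = src[i]; }
  return List::create(_["points"] = P, _["face"] = S, _["radius"] = r);
}

// ---- deterministic Euclidean minimum spanning tree -------------------------
// Kruskal on all pairwise distances; edges sorted by (weight, i, j) so ties
// break lexicographically on the edge index.
// [[Rcpp::export]]
NumericMatrix cpp_mst_edges(NumericMatrix X) {
  const int n = X.nrow(), d = X.ncol();
  if (n < 2) stop("need at least 2 points");
  struct Edge { double w; int i, j; };
  std::vector<Edge> edges;
  edges.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) { double dd = X(i,k) - X(j,k); s += dd * dd; }
      edges.push_back(Edge{ std::sqrt(s), i, j });
    }
  std::stable_sort(edges.begin(), edges.end(), [](const Edge& a, const Edge& b) {
    if (a.w != b.w) return a.w < b.w;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  std::vector<int> parent(n), rank_(n, 0);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  NumericMatrix out(n - 1, 3);
  int used = 0;
  for (const Edge& e : edges) {
    int ra = find(e.i), rb = find(e.j);
    if (ra == rb) continue;
    if (rank_[ra] < rank_[rb]) std::swap(ra, rb);
    parent[rb] = ra;
    if (rank_[ra] == rank_[rb]) ++rank_[ra];
    out(used, 0) = e.i + 1; out(used, 1) = e.j + 1; out(used, 2) = e.w;
    if (++used == n - 1) break;
  }
  return out;
}
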