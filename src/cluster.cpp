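#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Incremental energy-threshold clustering.
//
// Input probes MUST already be sorted in processing order: ascending energy,
// ties broken lexicographically on (x, y, z).  The threshold T starts at the
// minimum probe energy and is raised in steps of `step`; at each threshold
// every not-yet-active probe with e <= T is activated (in processing order)
// and joined, through a union-find, with every active probe within
// `linkage` (boundary inclusive).  A probe bridging several clusters merges
// them.  The procedure stops as soon as the cluster containing the probe
// just added reaches `p_num` members, or when every probe is active.
//
// Returns component labels (0 = never activated), the label of the capped
// cluster (0 if none reached p_num) and the final threshold.

struct DSU {
  std::vector<int> parent, sz;
  DSU(int n) : parent(n), sz(n, 1) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int a) {
    while (parent[a] != a) {
      parent[a] = parent[parent[a]];
      a = parent[a];
    }
    return a;
  }
  int unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return a;
    if (sz[a] < sz[b]) std::swap(a, b);
    parent[b] = a;
    sz[a] += sz[b];
    return a;
  }
};

// [[Rcpp::export]]
List cluster_probes_cpp(NumericMatrix xyz, NumericVector e, double linkage,
                        double step, int p_num, bool require_negative) {
  const int n = xyz.nrow();
  IntegerVector comp(n);
  if (n == 0)
    return List::create(_["comp"] = comp, _["capped"] = 0,
                        _["threshold"] = NA_REAL);
  if (require_negative && e[0] >= 0)
    return List::create(_["comp"] = comp, _["capped"] = 0,
                        _["threshold"] = NA_REAL);

  DSU dsu(n);
  std::unordered_map<int64_t, std::vector<int> > cells;
  cells.reserve(2 * n);
  const double cell = linkage, link2 = linkage * linkage;
  std::vector<char> active(n, 0);
  const double e0 = e[0];

  auto cell_of = [&](double v) { return (int64_t)std::floor(v / cell); };
  auto key_of = [&](int64_t cx, int64_t cy, int64_t cz) {
    return ((cx + 2097152) << 42) | ((cy + 2097152) << 21) | (cz + 2097152);
  };

  int i = 0, capped_root = -1;
  int64_t k = 0;
  double T = e0;
  bool done = false;
  while (!done) {
    while (i < n && e[i] <= T) {
      double x = xyz(i, 0), y = xyz(i, 1), z = xyz(i, 2);
      int64_t cx = cell_of(x), cy = cell_of(y), cz = cell_of(z);
      for (int64_t dx = -1; dx <= 1; ++dx)
        for (int64_t dy = -1; dy <= 1; ++dy)
          for (int64_t dz = -1; dz <= 1; ++dz) {
            auto it = cells.find(key_of(cx + dx, cy + dy, cz + dz));
            if (it == cells.end()) continue;
            const std::vector<int> &b = it->second;
            for (size_t t = 0; t < b.size(); ++t) {
              int j = b[t];
              double ddx = xyz(j, 0) - x, ddy = xyz(j, 1) - y,
                     ddz = xyz(j, 2) - z;
              if (ddx * ddx + ddy * ddy + ddz * ddz <= link2) dsu.unite(i, j);
            }
          }
      active[i] = 1;
      cells[key_of(cx, cy, cz)].push_back(i);
      int root = dsu.find(i);
      ++i;
      if (dsu.sz[root] >= p_num) {
        capped_root = root;
        done = true;
        break;
      }
    }
    if (done || i >= n) break;
    // raise the threshold just far enough to admit the next probe;
    // idle increments in between admit nothing and are skipped
    int64_t kn = (int64_t)std::ceil((e[i] - e0) / step - 1e-12);
    k = kn > k ? kn : k + 1;
    T = e0 + k * step;
  }

  // label components of active probes 1..m in order of first appearance
  std::vector<int> label(n, 0);
  int next = 0;
  for (int t = 0; t < n; ++t) {
    if (!active[t]) continue;
    int r = dsu.find(t);
    if (label[r] == 0) label[r] = ++next;
    comp[t] = label[r];
  }
  int capped = capped_root >= 0 ? label[dsu.find(capped_root)] : 0;
  return List::create(_["comp"] = comp, _["capped"] = capped,
                      _["threshold"] = T);
}
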