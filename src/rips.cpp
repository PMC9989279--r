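#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

// Vietoris-Rips persistence in degrees 0 and 1 for a point cloud given by its
// distance matrix.  Degree 0 comes from Kruskal/union-find over the edge
// filtration; degree 1 from mod-2 boundary-matrix reduction of the triangle
// columns against the cycle-creating edges.  The filtration is truncated at
// the enclosing radius min_i max_j d(i,j): past that value the complex is a
// cone, so every 1-cycle has died and H0 is a single class.

namespace {

struct DSU {
  std::vector<int> parent;
  explicit DSU(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    parent[b] = a;
    return true;
  }
};

struct Edge { double d; int i, j; };

// symmetric difference of two ascending int vectors (mod-2 column addition)
std::vector<int> sym_diff(const std::vector<int>& a, const std::vector<int>& b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  size_t p = 0, q = 0;
  while (p < a.size() && q < b.size()) {
    if (a[p] < b[q]) out.push_back(a[p++]);
    else if (b[q] < a[p]) out.push_back(b[q++]);
    else { ++p; ++q; }
  }
  while (p < a.size()) out.push_back(a[p++]);
  while (q < b.size()) out.push_back(b[q++]);
  return out;
}

} // namespace

// [[Rcpp::export(name = ".rips_persistence_cpp")]]
List rips_persistence_cpp(NumericMatrix dist, int maxdim) {
  const int n = dist.nrow();
  if (n < 2) stop("need at least 2 points");

  // enclosing radius: min over i of max over j != i of d(i, j)
  double thr = R_PosInf;
  for (int i = 0; i < n; ++i) {
    double mx = 0.0;
    for (int j = 0; j < n; ++j) if (j != i) mx = std::max(mx, dist(i, j));
    thr = std::min(thr, mx);
  }

  std::vector<Edge> edges;
  edges.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (dist(i, j) <= thr) edges.push_back({dist(i, j), i, j});
  std::sort(edges.begin(), edges.end(), [](const Edge& a, const Edge& b) {
    if (a.d != b.d) return a.d < b.d;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  const int ne = (int)edges.size();

  // ---- H0 via union-find ----------------------------------------------
  std::vector<double> h0_death;
  std::vector<char> is_cycle_edge(ne, 0);
  {
    DSU dsu(n);
    for (int e = 0; e < ne; ++e) {
      if (dsu.unite(edges[e].i, edges[e].j)) h0_death.push_back(edges[e].d);
      else is_cycle_edge[e] = 1;
    }
  }
  int n_components = n - (int)h0_death.size();  // essential H0 classes

  int n_h0 = (int)h0_death.size() + n_components;
  NumericMatrix H0(n_h0, 3);  // birth, death, essential
  for (size_t k = 0; k < h0_death.size(); ++k) {
    H0(k, 0) = 0.0; H0(k, 1) = h0_death[k]; H0(k, 2) = 0.0;
  }
  for (int k = 0; k < n_components; ++k) {
    int r = (int)h0_death.size() + k;
    H0(r, 0) = 0.0; H0(r, 1) = thr; H0(r, 2) = 1.0;
  }

  List out = List::create(_["H0"] = H0, _["threshold"] = thr);
  if (maxdim < 1) {
    out["H1"] = NumericMatrix(0, 3);
    return out;
  }

  // ---- H1: reduce triangle columns over the edge basis ----------------
  // edge lookup (i,j) -> sorted-edge index
  std::unordered_map<std::uint64_t, int> edge_id;
  edge_id.reserve(ne * 2);
  for (int e = 0; e < ne; ++e)
    edge_id[(std::uint64_t)edges[e].i * n + edges[e].j] = e;

  // enumerate triangles with diameter <= thr
  std::vector<double> tri_diam;
  std::vector<std::uint64_t> tri_key;  // i*n^2 + j*n + k packed
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dij = dist(i, j);
      if (dij > thr) continue;
      for (int k = j + 1; k < n; ++k) {
        double diam = std::max(dij, std::max(dist(i, k), dist(j, k)));
        if (diam <= thr) {
          tri_diam.push_back(diam);
          tri_key.push_back(((std::uint64_t)i * n + j) * n + k);
        }
      }
    }
  }
  std::vector<int> order(tri_diam.size());
  for (size_t t = 0; t < order.size(); ++t) order[t] = (int)t;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (tri_diam[a] != tri_diam[b]) return tri_diam[a] < tri_diam[b];
    return tri_key[a] < tri_key[b];
  });

  std::unordered_map<int, std::vector<int>> pivot_col;  // edge id -> reduced col
  std::unordered_map<int, double> pivot_death;          // edge id -> death value
  for (int idx : order) {
    std::uint64_t key = tri_key[idx];
    int k = (int)(key % n); key /= n;
    int j = (int)(key % n); key /= n;
    int i = (int)key;
    std::vector<int> col = {
      edge_id[(std::uint64_t)i * n + j],
      edge_id[(std::uint64_t)i * n + k],
      edge_id[(std::uint64_t)j * n + k]};
    std::sort(col.begin(), col.end());
    while (!col.empty()) {
      int piv = col.back();
      auto it = pivot_col.find(piv);
      if (it == pivot_col.end()) break;
      col = sym_diff(col, it->second);
    }
    if (!col.empty()) {
      int piv = col.back();
      pivot_death[piv] = tri_diam[idx];
      pivot_col.emplace(piv, std::move(col));
    }
  }

  std::vector<double> h1_birth, h1_death;
  std::vector<char> h1_ess;
  for (int e = 0; e < ne; ++e) {
    if (!is_cycle_edge[e]) continue;
    auto it = pivot_death.find(e);
    if (it != pivot_death.end()) {
      if (it->second > edges[e].d) {  // drop zero-persistence pairs
        h1_birth.push_back(edges[e].d);
        h1_death.push_back(it->second);
        h1_ess.push_back(0);
      }
    } else if (thr > edges[e].d) {
      // unpaired positive edge: essential class truncated at threshold
      h1_birth.push_back(edges[e].d);
      h1_death.push_back(thr);
      h1_ess.push_back(1);
    }
  }
  NumericMatrix H1((int)h1_birth.size(), 3);
  for (size_t r = 0; r < h1_birth.size(); ++r) {
    H1(r, 0) = h1_birth[r]; H1(r, 1) = h1_death[r]; H1(r, 2) = h1_ess[r] ? 1.0 : 0.0;
  }
  out["H1"] = H1;
  return out;
}
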