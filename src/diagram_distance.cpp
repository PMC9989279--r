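#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <limits>

using namespace Rcpp;

// Distances between persistence diagrams (rows = (birth, death)), with the
// usual convention that points may be matched to the diagonal at cost
// (death - birth) / 2 under the L-infinity ground metric.

namespace {

double linf(double b1, double d1, double b2, double d2) {
  return std::max(std::fabs(b1 - b2), std::fabs(d1 - d2));
}

// --- Dinic max-flow on a small network -------------------------------
struct Dinic {
  struct E { int to, cap, rev; };
  std::vector<std::vector<E>> g;
  std::vector<int> level, iter;
  explicit Dinic(int n) : g(n), level(n), iter(n) {}
  void add(int from, int to, int cap) {
    g[from].push_back({to, cap, (int)g[to].size()});
    g[to].push_back({from, 0, (int)g[from].size() - 1});
  }
  bool bfs(int s, int t) {
    std::fill(level.begin(), level.end(), -1);
    std::vector<int> q;
    level[s] = 0; q.push_back(s);
    for (size_t h = 0; h < q.size(); ++h) {
      int v = q[h];
      for (auto& e : g[v])
        if (e.cap > 0 && level[e.to] < 0) {
          level[e.to] = level[v] + 1;
          q.push_back(e.to);
        }
    }
    return level[t] >= 0;
  }
  int dfs(int v, int t, int f) {
    if (v == t) return f;
    for (int& i = iter[v]; i < (int)g[v].size(); ++i) {
      E& e = g[v][i];
      if (e.cap > 0 && level[v] < level[e.to]) {
        int d = dfs(e.to, t, std::min(f, e.cap));
        if (d > 0) { e.cap -= d; g[e.to][e.rev].cap += d; return d; }
      }
    }
    return 0;
  }
  int maxflow(int s, int t) {
    int flow = 0;
    while (bfs(s, t)) {
      std::fill(iter.begin(), iter.end(), 0);
      int f;
      while ((f = dfs(s, t, std::numeric_limits<int>::max())) > 0) flow += f;
    }
    return flow;
  }
};

// Can all points of A and B be matched (to each other or the diagonal)
// with every individual cost <= lam?  Diagonal copies are collapsed into
// two capacity super-nodes; feasibility is a max-flow of size nA + nB.
bool feasible(const NumericMatrix& A, const NumericMatrix& B, double lam) {
  const int nA = A.nrow(), nB = B.nrow();
  // nodes: 0 = S, 1..nA = A, nA+1 = DL, nA+2..nA+1+nB = B, nA+nB+2 = DR, +3 = T
  const int S = 0, DL = nA + 1, DR = nA + nB + 2, T = nA + nB + 3;
  Dinic net(nA + nB + 4);
  for (int i = 0; i < nA; ++i) net.add(S, 1 + i, 1);
  net.add(S, DL, nB);
  for (int j = 0; j < nB; ++j) net.add(DL + 1 + j, T, 1);
  net.add(DR, T, nA);
  const double eps = 1e-12;
  for (int i = 0; i < nA; ++i) {
    if ((A(i, 1) - A(i, 0)) / 2.0 <= lam + eps) net.add(1 + i, DR, 1);
    for (int j = 0; j < nB; ++j)
      if (linf(A(i, 0), A(i, 1), B(j, 0), B(j, 1)) <= lam + eps)
        net.add(1 + i, DL + 1 + j, 1);
  }
  for (int j = 0; j < nB; ++j)
    if ((B(j, 1) - B(j, 0)) / 2.0 <= lam + eps) net.add(DL, DL + 1 + j, 1);
  net.add(DL, DR, std::min(nA, nB));
  return net.maxflow(S, T) == nA + nB;
}

} // namespace

// [[Rcpp::export(name = ".bottleneck_cpp")]]
double bottleneck_cpp(NumericMatrix A, NumericMatrix B) {
  const int nA = A.nrow(), nB = B.nrow();
  if (nA == 0 && nB == 0) return 0.0;
  std::vector<double> cand;
  cand.push_back(0.0);
  for (int i = 0; i < nA; ++i) cand.push_back((A(i, 1) - A(i, 0)) / 2.0);
  for (int j = 0; j < nB; ++j) cand.push_back((B(j, 1) - B(j, 0)) / 2.0);
  for (int i = 0; i < nA; ++i)
    for (int j = 0; j < nB; ++j)
      cand.push_back(linf(A(i, 0), A(i, 1), B(j, 0), B(j, 1)));
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
  int lo = 0, hi = (int)cand.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (feasible(A, B, cand[mid])) hi = mid; else lo = mid + 1;
  }
  return cand[lo];
}

// [[Rcpp::export(name = ".wasserstein_cpp")]]
double wasserstein_cpp(NumericMatrix A, NumericMatrix B, double q) {
  const int nA = A.nrow(), nB = B.nrow();
  const int n = nA + nB;
  if (n == 0) return 0.0;
  // augmented square assignment: A + diag copies  vs  B + diag copies
  std::vector<std::vector<double>> C(n, std::vector<double>(n, 0.0));
  for (int i = 0; i < nA; ++i) {
    for (int j = 0; j < nB; ++j)
      C[i][j] = std::pow(linf(A(i, 0), A(i, 1), B(j, 0), B(j, 1)), q);
    double dia = std::pow((A(i, 1) - A(i, 0)) / 2.0, q);
    for (int j = nB; j < n; ++j) C[i][j] = dia;
  }
  for (int i = nA; i < n; ++i)
    for (int j = 0; j < nB; ++j)
      C[i][j] = std::pow((B(j, 1) - B(j, 0)) / 2.0, q);
  // Hungarian algorithm (Jonker-Volgenant style potentials), O(n^3)
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j)
        if (!used[j]) {
          double cur = C[i0 - 1][j - 1] - u[i0] - v[j];
          if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
          if (minv[j] < delta) { delta = minv[j]; j1 = j; }
        }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  double total = 0.0;
  for (int j = 1; j <= n; ++j) total += C[p[j] - 1][j - 1];
  return std::pow(total, 1.0 / q);
}
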