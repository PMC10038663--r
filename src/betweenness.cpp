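#include <Rcpp.h>
using namespace Rcpp;

// Unweighted directed betweenness, CB_i = sum over ordered pairs (s,u),
// s != u, i interior, of sigma_su(i) / sigma_su. Unnormalized; unreachable
// pairs contribute 0; self-loops must be removed by the caller.

typedef std::vector<std::vector<int> > AdjList;

static void brandes_cb(const AdjList& adj, int n, std::vector<double>& cb) {
  std::fill(cb.begin(), cb.end(), 0.0);
  std::vector<int> dist(n), sigma(n), order, queue(n);
  std::vector<double> delta(n);
  std::vector<std::vector<int> > pred(n);
  order.reserve(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0);
    for (int i = 0; i < n; ++i) pred[i].clear();
    order.clear();
    int qh = 0, qt = 0;
    queue[qt++] = s; dist[s] = 0; sigma[s] = 1;
    while (qh < qt) {
      int v = queue[qh++];
      order.push_back(v);
      for (size_t k = 0; k < adj[v].size(); ++k) {
        int w = adj[v][k];
        if (dist[w] < 0) { dist[w] = dist[v] + 1; queue[qt++] = w; }
        if (dist[w] == dist[v] + 1) { sigma[w] += sigma[v]; pred[w].push_back(v); }
      }
    }
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int k = (int)order.size() - 1; k >= 0; --k) {
      int w = order[k];
      for (size_t j = 0; j < pred[w].size(); ++j) {
        int v = pred[w][j];
        delta[v] += ((double)sigma[v] / (double)sigma[w]) * (1.0 + delta[w]);
      }
      if (w != s) cb[w] += delta[w];
    }
  }
}

// Independent oracle: enumerate every simple path between each ordered pair
// by depth-first search, keep only the shortest ones, and credit interior
// vertices with their path share. Exponential, for small n only.
struct PathEnum {
  const AdjList* adj;
  int n, target, best;
  std::vector<int> path;
  std::vector<bool> onpath;
  std::vector<std::vector<int> > shortest; // interior vertices per shortest path

  void dfs(int v) {
    if (v == target) {
      int len = (int)path.size() - 1;
      if (len < best) { best = len; shortest.clear(); }
      if (len == best) {
        std::vector<int> interior(path.begin() + 1, path.end() - 1);
        shortest.push_back(interior);
      }
      return;
    }
    if ((int)path.size() - 1 >= best) return; // cannot improve
    const std::vector<int>& nb = (*adj)[v];
    for (size_t k = 0; k < nb.size(); ++k) {
      int w = nb[k];
      if (onpath[w]) continue;
      onpath[w] = true; path.push_back(w);
      dfs(w);
      path.pop_back(); onpath[w] = false;
    }
  }
};

static void brute_cb(const AdjList& adj, int n, std::vector<double>& cb) {
  std::fill(cb.begin(), cb.end(), 0.0);
  PathEnum pe;
  pe.adj = &adj; pe.n = n;
  for (int s = 0; s < n; ++s) {
    for (int u = 0; u < n; ++u) {
      if (s == u) continue;
      pe.target = u; pe.best = n; // any simple path has length <= n-1
      pe.path.assign(1, s);
      pe.onpath.assign(n, false);
      pe.onpath[s] = true;
      pe.shortest.clear();
      pe.dfs(s);
      size_t m = pe.shortest.size();
      if (m == 0) continue;
      for (size_t p = 0; p < m; ++p) {
        const std::vector<int>& interior = pe.shortest[p];
        for (size_t j = 0; j < interior.size(); ++j)
          cb[interior[j]] += 1.0 / (double)m;
      }
    }
  }
}

static AdjList matrix_to_adj(const IntegerMatrix& adj_mat) {
  int n = adj_mat.nrow();
  AdjList adj(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && adj_mat(i, j) != 0) adj[i].push_back(j);
  return adj;
}

// [[Rcpp::export]]
NumericVector cpp_betweenness(IntegerMatrix adj_mat) {
  int n = adj_mat.nrow();
  AdjList adj = matrix_to_adj(adj_mat);
  std::vector<double> cb(n);
  brandes_cb(adj, n, cb);
  return NumericVector(cb.begin(), cb.end());
}

// [[Rcpp::export]]
NumericVector cpp_betweenness_brute(IntegerMatrix adj_mat) {
  int n = adj_mat.nrow();
  AdjList adj = matrix_to_adj(adj_mat);
  std::vector<double> cb(n);
  brute_cb(adj, n, cb);
  return NumericVector(cb.begin(), cb.end());
}

// Exhaustive agreement check over every labelled digraph (no self-loops)
// on n nodes: 2^(n(n-1)) graphs. Returns the number of graphs checked and
// the maximum absolute discrepancy between the two routes.
// [[Rcpp::export]]
List cpp_check_betweenness_exhaustive(int n) {
  if (n < 1 || n > 5) stop("exhaustive check supports 1 <= n <= 5");
  int m = n * (n - 1);
  long long total = 1LL << m;
  std::vector<std::pair<int, int> > slots;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j) slots.push_back(std::make_pair(i, j));
  double maxdiff = 0.0;
  std::vector<double> cb1(n), cb2(n);
  AdjList adj(n);
  for (long long mask = 0; mask < total; ++mask) {
    for (int i = 0; i < n; ++i) adj[i].clear();
    for (int b = 0; b < m; ++b)
      if (mask & (1LL << b)) adj[slots[b].first].push_back(slots[b].second);
    brandes_cb(adj, n, cb1);
    brute_cb(adj, n, cb2);
    for (int i = 0; i < n; ++i) {
      double d = std::fabs(cb1[i] - cb2[i]);
      if (d > maxdiff) maxdiff = d;
    }
    if ((mask & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["n_graphs"] = (double)total, _["max_abs_diff"] = maxdiff);
}
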