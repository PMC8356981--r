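#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Degree-preserving randomisation of an undirected graph by double-edge
// swaps, rejecting any swap that would disconnect the graph (checked with a
// BFS after tentatively applying the swap). Randomness comes from R's RNG.
//
// edges: m x 2 integer matrix of 1-based endpoints (i < j).
// Returns the rewired m x 2 edge matrix (1-based).

static bool connected_bfs(const std::vector<std::vector<bool>> &adj, int n) {
  std::vector<int> stack;
  std::vector<bool> seen(n, false);
  stack.push_back(0);
  seen[0] = true;
  int cnt = 1;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    const std::vector<bool> &row = adj[v];
    for (int u = 0; u < n; ++u) {
      if (row[u] && !seen[u]) {
        seen[u] = true;
        ++cnt;
        stack.push_back(u);
      }
    }
  }
  return cnt == n;
}

// [[Rcpp::export(name = ".rewireConnected")]]
IntegerMatrix rewire_connected(IntegerMatrix edges, int n, int nAttempts) {
  const int m = edges.nrow();
  std::vector<int> ea(m), eb(m);
  std::vector<std::vector<bool>> adj(n, std::vector<bool>(n, false));
  for (int e = 0; e < m; ++e) {
    ea[e] = edges(e, 0) - 1;
    eb[e] = edges(e, 1) - 1;
    adj[ea[e]][eb[e]] = adj[eb[e]][ea[e]] = true;
  }

  for (int att = 0; att < nAttempts; ++att) {
    int e1 = (int)(unif_rand() * m); if (e1 >= m) e1 = m - 1;
    int e2 = (int)(unif_rand() * m); if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int a = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
    // orient one edge at random so both swap patterns are reachable
    if (unif_rand() < 0.5) std::swap(c, d);
    // proposed: (a,d) and (c,b)
    if (a == d || c == b || a == c || b == d) continue;
    if (adj[a][d] || adj[c][b]) continue;
    adj[a][b] = adj[b][a] = false;
    adj[c][d] = adj[d][c] = false;
    adj[a][d] = adj[d][a] = true;
    adj[c][b] = adj[b][c] = true;
    if (connected_bfs(adj, n)) {
      ea[e1] = a; eb[e1] = d;
      ea[e2] = c; eb[e2] = b;
    } else { // revert
      adj[a][d] = adj[d][a] = false;
      adj[c][b] = adj[b][c] = false;
      adj[a][b] = adj[b][a] = true;
      adj[c][d] = adj[d][c] = true;
    }
  }

  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) {
    int i = ea[e], j = eb[e];
    if (i > j) std::swap(i, j);
    out(e, 0) = i + 1;
    out(e, 1) = j + 1;
  }
  return out;
}
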