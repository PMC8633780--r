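#include <Rcpp.h>
#include <map>
#include <vector>
using namespace Rcpp;

// (6,6) body-bar pebble game. Every body carries 6 pebbles (degrees of
// freedom); a bar between two bodies is independent iff 7 pebbles can be
// gathered on its endpoints, and accepting it consumes one pebble and
// orients the bar away from the paying body. Pebble searches are directed
// depth-first searches; moving a pebble back along the search path reverses
// the edges on that path.

class Game {
public:
  int n;
  std::vector<int> peb;
  std::vector< std::map<int,int> > out; // directed multi-edge counts
  std::vector<int> visited;
  std::vector<int> parent;
  int stamp;

  Game(int n_) : n(n_), peb(n_, 6), out(n_), visited(n_, 0), parent(n_, -1), stamp(0) {}

  // try to bring one pebble onto `start`; pebbles on b1/b2 are frozen
  bool findPebble(int start, int b1, int b2) {
    ++stamp;
    visited[start] = stamp;
    if (b1 >= 0) visited[b1] = stamp;
    if (b2 >= 0) visited[b2] = stamp;
    std::vector<int> stack;
    stack.push_back(start);
    parent[start] = -1;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      for (std::map<int,int>::iterator it = out[u].begin(); it != out[u].end(); ++it) {
        int w = it->first;
        if (it->second <= 0 || visited[w] == stamp) continue;
        visited[w] = stamp;
        parent[w] = u;
        if (peb[w] > 0) {
          peb[w]--;
          int cur = w;
          while (parent[cur] != -1) {
            int p = parent[cur];
            out[p][cur]--;
            if (out[p][cur] == 0) out[p].erase(cur);
            out[cur][p]++;
            cur = p;
          }
          peb[start]++;
          return true;
        }
        stack.push_back(w);
      }
    }
    return false;
  }

  int gatherPair(int u, int v, int target) {
    while (peb[u] + peb[v] < target) {
      bool moved = false;
      if (peb[u] < 6 && findPebble(u, u, v)) moved = true;
      else if (peb[v] < 6 && findPebble(v, u, v)) moved = true;
      if (!moved) break;
    }
    return peb[u] + peb[v];
  }

  bool insertBar(int u, int v) {
    if (u == v) return false;
    int tot = gatherPair(u, v, 7);
    if (tot >= 7) {
      // peb[u] >= 1 here: a single body holds at most 6 pebbles
      peb[u]--;
      out[u][v]++;
      return true;
    }
    return false;
  }
};

struct UF {
  std::vector<int> p;
  UF(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  void unite(int a, int b) { p[find(a)] = find(b); }
};

// bars: m x 3 integer matrix (body_i, body_j, multiplicity), 1-based bodies.
// Bars are inserted one unit bar at a time in row order.
// [[Rcpp::export(name = ".pebble_run_cpp")]]
List pebble_run_cpp(int nBodies, IntegerMatrix bars, bool clusters = true) {
  Game g(nBodies);
  int m = bars.nrow();
  IntegerVector acceptedPerEdge(m);
  int accepted = 0;
  for (int e = 0; e < m; ++e) {
    int u = bars(e, 0) - 1, v = bars(e, 1) - 1, mult = bars(e, 2);
    if (u < 0 || u >= nBodies || v < 0 || v >= nBodies)
      stop("bar endpoint out of range");
    int acc = 0;
    for (int b = 0; b < mult; ++b)
      if (g.insertBar(u, v)) acc++;
    acceptedPerEdge[e] = acc;
    accepted += acc;
  }
  int freePebbles = 6 * nBodies - accepted;

  IntegerVector clusterOf(nBodies);
  if (clusters) {
    UF uf(nBodies);
    // unique body pairs, in first-seen order
    std::map< std::pair<int,int>, bool > seen;
    std::vector< std::pair<int,int> > pairs;
    for (int e = 0; e < m; ++e) {
      int u = bars(e, 0) - 1, v = bars(e, 1) - 1;
      if (u == v) continue;
      std::pair<int,int> key(std::min(u, v), std::max(u, v));
      if (!seen[key]) { seen[key] = true; pairs.push_back(key); }
    }
    std::vector<char> inD(nBodies);
    for (size_t k = 0; k < pairs.size(); ++k) {
      int u = pairs[k].first, v = pairs[k].second;
      if (uf.find(u) == uf.find(v)) continue;
      int tot = g.gatherPair(u, v, 7);
      if (tot >= 7) continue; // pair is mutually flexible
      // rigid pair: its rigid cluster is the set of bodies from which no
      // free pebble (outside u,v) is reachable by a directed path
      std::fill(inD.begin(), inD.end(), 0);
      std::vector<int> stack;
      // reverse reachability: BFS over in-edges, seeded at free-pebble bodies
      // build reverse adjacency lazily
      std::vector< std::vector<int> > rev(nBodies);
      for (int a = 0; a < nBodies; ++a)
        for (std::map<int,int>::iterator it = g.out[a].begin(); it != g.out[a].end(); ++it)
          if (it->second > 0) rev[it->first].push_back(a);
      for (int w = 0; w < nBodies; ++w)
        if (g.peb[w] > 0 && w != u && w != v) { inD[w] = 1; stack.push_back(w); }
      while (!stack.empty()) {
        int a = stack.back(); stack.pop_back();
        for (size_t q = 0; q < rev[a].size(); ++q) {
          int b = rev[a][q];
          if (!inD[b]) { inD[b] = 1; stack.push_back(b); }
        }
      }
      for (int w = 0; w < nBodies; ++w)
        if (!inD[w]) uf.unite(w, u);
    }
    for (int i = 0; i < nBodies; ++i) clusterOf[i] = uf.find(i) + 1;
  }

  return List::create(
    _["accepted"] = accepted,
    _["acceptedPerEdge"] = acceptedPerEdge,
    _["freePebbles"] = freePebbles,
    _["floppyModes"] = freePebbles - 6,
    _["clusterOf"] = clusterOf);
}
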