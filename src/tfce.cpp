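#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// CSR adjacency from a 0-based edge list
struct Adjacency {
  std::vector<int> ptr, nbr;
  Adjacency(const IntegerMatrix& edges, int n) {
    std::vector<int> deg(n, 0);
    for (int e = 0; e < edges.nrow(); ++e) {
      ++deg[edges(e, 0)];
      ++deg[edges(e, 1)];
    }
    ptr.assign(n + 1, 0);
    for (int i = 0; i < n; ++i) ptr[i + 1] = ptr[i] + deg[i];
    nbr.assign(ptr[n], 0);
    std::vector<int> fill(n, 0);
    for (int e = 0; e < edges.nrow(); ++e) {
      int a = edges(e, 0), b = edges(e, 1);
      nbr[ptr[a] + fill[a]++] = b;
      nbr[ptr[b] + fill[b]++] = a;
    }
  }
};

// Workspace reused across maps in a batch
struct TfceWork {
  std::vector<int> order, parent, size, roots;
  std::vector<double> acc, delta, val;
  std::vector<char> active;
};

// no path compression: the parent links double as the merge-history tree
// that carries the per-node offsets, so they must stay intact. Union by
// size keeps chains O(log n).
static inline int uf_find(const std::vector<int>& parent, int x) {
  while (parent[x] != x) x = parent[x];
  return x;
}

// One-tailed TFCE of the positive part of `stat`, written into w.val.
// Heights are processed in descending order with a union-find over the
// growing supra-threshold set; each cluster's per-step increment
// extent^E * h^H * dh is accumulated lazily at its root, and nodes record
// an offset when clusters merge, so every node's integral is recovered at
// the end from its merge path. This touches each edge O(1) times instead
// of once per integration step.
static void tfce_tail(const std::vector<double>& stat, const Adjacency& adj,
                      double E, double H, int n_steps, double dh_in,
                      TfceWork& w) {
  const int n = stat.size();
  w.val.assign(n, 0.0);
  double hmax = 0.0;
  for (int i = 0; i < n; ++i) if (stat[i] > hmax) hmax = stat[i];
  if (hmax <= 0.0) return;
  double dh = dh_in > 0.0 ? dh_in : hmax / n_steps;
  int steps = dh_in > 0.0 ? (int)std::ceil(hmax / dh) : n_steps;

  // positive-stat nodes sorted by descending height
  w.order.clear();
  for (int i = 0; i < n; ++i) if (stat[i] > 0.0) w.order.push_back(i);
  std::sort(w.order.begin(), w.order.end(),
            [&stat](int a, int b) { return stat[a] > stat[b]; });

  w.parent.resize(n);
  w.size.resize(n);
  w.acc.resize(n);
  w.delta.assign(n, 0.0);
  w.active.assign(n, 0);
  w.roots.clear();

  size_t next = 0; // next node to activate in descending-stat order
  int n_dead = 0;  // absorbed roots still sitting in w.roots
  for (int s = steps; s >= 1; --s) {
    double h = s * dh;
    if (h > hmax) h = hmax; // user-supplied dh may overshoot the top
    // activate nodes reaching above this height and union with neighbors
    while (next < w.order.size() && stat[w.order[next]] >= h) {
      int u = w.order[next++];
      w.parent[u] = u;
      w.size[u] = 1;
      w.acc[u] = 0.0;
      w.delta[u] = 0.0;
      w.active[u] = 1;
      w.roots.push_back(u);
      for (int k = adj.ptr[u]; k < adj.ptr[u + 1]; ++k) {
        int v = adj.nbr[k];
        if (!w.active[v]) continue;
        int ru = uf_find(w.parent, u);
        int rv = uf_find(w.parent, v);
        if (ru == rv) continue;
        if (w.size[ru] < w.size[rv]) std::swap(ru, rv);
        // rv's members keep what they have and from now on accrue ru's
        // future additions
        w.delta[rv] = w.acc[rv] - w.acc[ru];
        w.parent[rv] = ru;
        w.size[ru] += w.size[rv];
        ++n_dead;
      }
    }
    // credit every current cluster
    double hh = std::pow(h, H) * dh;
    if (n_dead * 2 > (int)w.roots.size()) {
      size_t keep = 0;
      for (size_t i = 0; i < w.roots.size(); ++i) {
        if (w.parent[w.roots[i]] == w.roots[i]) w.roots[keep++] = w.roots[i];
      }
      w.roots.resize(keep);
      n_dead = 0;
    }
    for (size_t i = 0; i < w.roots.size(); ++i) {
      int r = w.roots[i];
      if (w.parent[r] != r) continue;
      w.acc[r] += (E == 0.5 ? std::sqrt((double)w.size[r])
                            : std::pow((double)w.size[r], E)) * hh;
    }
  }
  // resolve each node's integral: a final root holds acc[root]; an
  // absorbed node holds its absorber's resolved value plus its recorded
  // offset. Walk each unresolved chain up to a resolved ancestor, then
  // unwind.
  // only nodes that actually activated (order[0..next)) carry state;
  // everything below the lowest height keeps val = 0
  std::vector<char> done(n, 0);
  std::vector<int> chain;
  for (size_t i = 0; i < next; ++i) {
    int u = w.order[i];
    if (done[u]) continue;
    chain.clear();
    int x = u;
    while (!done[x] && w.parent[x] != x) {
      chain.push_back(x);
      x = w.parent[x];
    }
    if (!done[x]) { // x is a final root
      w.val[x] = w.acc[x];
      done[x] = 1;
    }
    for (size_t k = chain.size(); k-- > 0; ) {
      int c = chain[k];
      w.val[c] = w.val[w.parent[c]] + w.delta[c];
      done[c] = 1;
    }
  }
}

// [[Rcpp::export]]
NumericVector tfce_enhance_cpp(NumericVector stat, IntegerMatrix edges,
                               double E, double H, int n_steps,
                               double dh) {
  const int n = stat.size();
  Adjacency adj(edges, n);
  TfceWork w;
  std::vector<double> pos(n), neg(n);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double v = NumericVector::is_na(stat[i]) ? 0.0 : stat[i];
    pos[i] = v > 0 ? v : 0.0;
    neg[i] = v < 0 ? -v : 0.0;
  }
  tfce_tail(pos, adj, E, H, n_steps, dh, w);
  for (int i = 0; i < n; ++i) out[i] = w.val[i];
  tfce_tail(neg, adj, E, H, n_steps, dh, w);
  for (int i = 0; i < n; ++i) out[i] -= w.val[i];
  return out;
}

// max |TFCE| per row of `maps` (rows are permutation statistic maps)
// [[Rcpp::export]]
NumericVector tfce_max_batch_cpp(NumericMatrix maps, IntegerMatrix edges,
                                 double E, double H, int n_steps) {
  const int n = maps.ncol();
  Adjacency adj(edges, n);
  TfceWork w;
  NumericVector res(maps.nrow());
  std::vector<double> pos(n), neg(n);
  for (int r = 0; r < maps.nrow(); ++r) {
    for (int i = 0; i < n; ++i) {
      double v = NumericMatrix::is_na(maps(r, i)) ? 0.0 : maps(r, i);
      pos[i] = v > 0 ? v : 0.0;
      neg[i] = v < 0 ? -v : 0.0;
    }
    double mx = 0.0;
    tfce_tail(pos, adj, E, H, n_steps, -1.0, w);
    for (int i = 0; i < n; ++i) if (w.val[i] > mx) mx = w.val[i];
    tfce_tail(neg, adj, E, H, n_steps, -1.0, w);
    for (int i = 0; i < n; ++i) if (w.val[i] > mx) mx = w.val[i];
    res[r] = mx;
  }
  return res;
}
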