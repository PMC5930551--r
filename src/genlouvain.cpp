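// Generalized Louvain optimisation of categorical multislice modularity.
//
// Quality (unnormalised; the 1/2mu factor does not affect the argmax):
//   sum_{ijs} (A_ijs - gamma * k_is k_js / (2 m_s)) delta(g_is, g_js)
//     + omega * sum_i sum_{s != r} delta(g_is, g_ir)
// Intra-slice edges keep a per-slice configuration null model; inter-slice
// (categorical, all-pairs) coupling edges carry weight omega and no null
// term. Vertices are node-slices; aggregation sums per-slice degrees so the
// null model stays exact across levels.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

// splitmix64 finaliser: decorrelates nearby seeds.
inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Deterministic RNG (xorshift64* on a splitmix64-scrambled state):
// identical streams on every platform, uncorrelated for nearby seeds.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) {
    s = splitmix64(splitmix64(seed));
    if (!s) s = 0x9E3779B97F4A7C15ULL;
  }
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

struct Graph {
  int V = 0, S = 0;
  std::vector<std::vector<std::pair<int, double> > > adj; // off-self edges
  std::vector<double> self;                               // internal weight
  // per-vertex sparse slice-degree: (slice, intra-slice degree sum)
  std::vector<std::vector<std::pair<int, double> > > kdeg;
};

class Optimiser {
public:
  Optimiser(double gamma, const std::vector<double>& twom, Rng& rng)
    : gamma_(gamma), twom_(twom), rng_(rng) {}

  // One Louvain level: move phase until stable; returns membership 0..C-1.
  std::vector<int> level(const Graph& g, bool& improved) {
    int V = g.V, S = g.S;
    std::vector<int> comm(V);
    for (int v = 0; v < V; ++v) comm[v] = v;
    // community slice-degree sums
    std::vector<double> Kc((size_t)V * S, 0.0);
    for (int v = 0; v < V; ++v)
      for (auto& sk : g.kdeg[v]) Kc[(size_t)v * S + sk.first] += sk.second;

    std::vector<double> wc(V, 0.0); // scratch: weight to community
    std::vector<int> touched;
    std::vector<int> order(V);
    for (int v = 0; v < V; ++v) order[v] = v;

    improved = false;
    bool moved = true;
    int sweep = 0;
    while (moved && sweep < 100) {
      moved = false;
      ++sweep;
      for (int v = V - 1; v > 0; --v) std::swap(order[v], order[rng_.below(v + 1)]);
      for (int idx = 0; idx < V; ++idx) {
        int v = order[idx];
        int cv = comm[v];
        // weights from v to neighbouring communities
        touched.clear();
        for (auto& e : g.adj[v]) {
          int c = comm[e.first];
          if (wc[c] == 0.0) touched.push_back(c);
          wc[c] += e.second;
        }
        if (wc[cv] == 0.0) touched.push_back(cv); // ensure own comm considered
        // remove v from its community
        for (auto& sk : g.kdeg[v]) Kc[(size_t)cv * S + sk.first] -= sk.second;
        double best_gain = gain(g, v, cv, wc[cv], Kc);
        int best = cv;
        for (int c : touched) {
          if (c == cv) continue;
          double gn = gain(g, v, c, wc[c], Kc);
          if (gn > best_gain + 1e-12) { best_gain = gn; best = c; }
        }
        for (int c : touched) wc[c] = 0.0;
        for (auto& sk : g.kdeg[v]) Kc[(size_t)best * S + sk.first] += sk.second;
        if (best != cv) { comm[v] = best; moved = true; improved = true; }
      }
    }
    return comm;
  }

private:
  double gain(const Graph& g, int v, int c, double w_vc,
              const std::vector<double>& Kc) {
    double null_term = 0.0;
    for (auto& sk : g.kdeg[v]) {
      double tm = twom_[sk.first];
      if (tm > 0) null_term += sk.second * Kc[(size_t)c * g.S + sk.first] / tm;
    }
    return w_vc - gamma_ * null_term;
  }
  double gamma_;
  const std::vector<double>& twom_;
  Rng& rng_;
};

Graph aggregate(const Graph& g, const std::vector<int>& comm, int C) {
  Graph h;
  h.V = C; h.S = g.S;
  h.adj.assign(C, {});
  h.self.assign(C, 0.0);
  std::vector<std::vector<double> > kd(C, std::vector<double>(g.S, 0.0));
  std::vector<double> row(C, 0.0);
  std::vector<int> touched;
  // group vertices by community
  std::vector<std::vector<int> > members(C);
  for (int v = 0; v < g.V; ++v) members[comm[v]].push_back(v);
  for (int c = 0; c < C; ++c) {
    touched.clear();
    for (int v : members[c]) {
      h.self[c] += g.self[v];
      for (auto& sk : g.kdeg[v]) kd[c][sk.first] += sk.second;
      for (auto& e : g.adj[v]) {
        int d = comm[e.first];
        if (d == c) { h.self[c] += e.second; continue; } // counted both dirs
        if (row[d] == 0.0) touched.push_back(d);
        row[d] += e.second;
      }
    }
    for (int d : touched) {
      h.adj[c].push_back({d, row[d]});
      row[d] = 0.0;
    }
  }
  h.kdeg.assign(C, {});
  for (int c = 0; c < C; ++c)
    for (int s = 0; s < g.S; ++s)
      if (kd[c][s] != 0.0) h.kdeg[c].push_back({s, kd[c][s]});
  return h;
}

} // namespace

// [[Rcpp::export(name = ".genlouvain_cpp")]]
IntegerMatrix genlouvain_cpp(int n, int S,
                             IntegerVector ei, IntegerVector ej,
                             IntegerVector es,
                             double gamma, double omega, double seed) {
  // Build level-0 graph: vertex id = (s-1)*n + (i-1)
  Graph g;
  g.V = n * S; g.S = S;
  g.adj.assign(g.V, {});
  g.self.assign(g.V, 0.0);
  std::vector<double> twom(S, 0.0);
  std::vector<double> deg(g.V, 0.0);
  int E = ei.size();
  for (int e = 0; e < E; ++e) {
    int s = es[e] - 1;
    int u = s * n + (ei[e] - 1);
    int v = s * n + (ej[e] - 1);
    g.adj[u].push_back({v, 1.0});
    g.adj[v].push_back({u, 1.0});
    deg[u] += 1.0; deg[v] += 1.0;
    twom[s] += 2.0;
  }
  if (omega > 0 && S > 1) {
    for (int i = 0; i < n; ++i)
      for (int s = 0; s < S; ++s)
        for (int r = 0; r < S; ++r)
          if (r != s) g.adj[s * n + i].push_back({r * n + i, omega});
  }
  g.kdeg.assign(g.V, {});
  for (int v = 0; v < g.V; ++v)
    if (deg[v] > 0) g.kdeg[v].push_back({v / n, deg[v]});

  Rng rng((uint64_t)seed);
  Optimiser opt(gamma, twom, rng);

  std::vector<int> final_comm(g.V);
  for (int v = 0; v < g.V; ++v) final_comm[v] = v;

  Graph cur = g;
  for (int lev = 0; lev < 50; ++lev) {
    bool improved = false;
    std::vector<int> comm = opt.level(cur, improved);
    // relabel 0..C-1
    std::vector<int> map(cur.V, -1);
    int C = 0;
    for (int v = 0; v < cur.V; ++v) if (map[comm[v]] < 0) map[comm[v]] = C++;
    for (int v = 0; v < cur.V; ++v) comm[v] = map[comm[v]];
    for (int v = 0; v < g.V; ++v) final_comm[v] = comm[final_comm[v]];
    if (!improved || C == cur.V) break;
    cur = aggregate(cur, comm, C);
  }

  IntegerMatrix memb(n, S);
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < n; ++i)
      memb(i, s) = final_comm[s * n + i] + 1;
  return memb;
}

// Hash-derive a child seed (in 1..2^31-2) from a master seed and a stream
// index; nearby (seed, index) pairs give uncorrelated children.
// [[Rcpp::export(name = ".hash_seed_cpp")]]
double hash_seed_cpp(double seed, double index) {
  uint64_t h = splitmix64(((uint64_t)seed << 32) ^ (uint64_t)index);
  return (double)(h % 2147483645ULL) + 1.0;
}

// Fraction of slices in which each ROI pair shares a module label.
// [[Rcpp::export(name = ".colabel_fraction_cpp")]]
NumericMatrix colabel_fraction_cpp(IntegerMatrix memb) {
  int n = memb.nrow(), S = memb.ncol();
  NumericMatrix P(n, n);
  for (int s = 0; s < S; ++s)
    for (int j = 0; j < n; ++j)
      for (int i = j; i < n; ++i)
        if (memb(i, s) == memb(j, s)) P(i, j) += 1.0;
  for (int j = 0; j < n; ++j)
    for (int i = j; i < n; ++i) {
      double v = P(i, j) / S;
      P(i, j) = v; P(j, i) = v;
    }
  return P;
}
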