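#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Union-find with rollback, used by the spanning-tree branch-and-bound.
struct DSU {
  std::vector<int> parent, size;
  std::vector<std::pair<int, int>> hist; // (absorbed root, surviving root)
  explicit DSU(int n) : parent(n), size(n, 1) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) x = parent[x];
    return x;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a; size[a] += size[b];
    hist.push_back(std::make_pair(b, a));
    return true;
  }
  size_t mark() const { return hist.size(); }
  void rollback(size_t m) {
    while (hist.size() > m) {
      std::pair<int, int> pr = hist.back(); hist.pop_back();
      parent[pr.first] = pr.first; size[pr.second] -= size[pr.first];
    }
  }
};

namespace {

struct EnumCtx {
  int E, V;
  std::vector<int> eu, ev;
  DSU *dsu;
  std::vector<int> scratch; // reusable parent array for connectivity checks
  std::vector<uint32_t> *out;
};

// Is (current forest, whose components the main DSU already tracks) +
// (edges with index >= i) connected over all V vertices?  nin = number of
// forest edges, so the forest has V - nin components.
bool remainder_connected(EnumCtx &ctx, int i, int nin) {
  std::vector<int> &par = ctx.scratch;
  par.assign(ctx.dsu->parent.begin(), ctx.dsu->parent.end());
  int comps = ctx.V - nin;
  for (int e = i; e < ctx.E && comps > 1; ++e) {
    int a = par[ctx.eu[e]], b = par[ctx.ev[e]];
    while (par[a] != a) a = par[a];
    while (par[b] != b) b = par[b];
    if (a != b) { par[b] = a; --comps; }
  }
  return comps == 1;
}

// Invariant on entry: forest + {edges >= i} is connected, so at least one
// spanning tree completes the current partial choice.  Each spanning tree is
// reached exactly once.
void enum_rec(EnumCtx &ctx, int i, int nin, uint32_t mask) {
  if (nin == ctx.V - 1) { ctx.out->push_back(mask); return; }
  // include edge i if it does not close a cycle
  int ra = ctx.dsu->find(ctx.eu[i]), rb = ctx.dsu->find(ctx.ev[i]);
  if (ra != rb) {
    size_t m = ctx.dsu->mark();
    ctx.dsu->unite(ctx.eu[i], ctx.ev[i]);
    enum_rec(ctx, i + 1, nin + 1, mask | (uint32_t(1) << i));
    ctx.dsu->rollback(m);
  }
  // exclude edge i only when a spanning tree is still possible without it
  if (remainder_connected(ctx, i + 1, nin))
    enum_rec(ctx, i + 1, nin, mask);
}

// lexicographic order on ascending edge-index lists of equal cardinality
inline bool lex_less(uint32_t a, uint32_t b) {
  uint32_t d = a ^ b;
  if (d == 0) return false;
  return (a & (d & (~d + 1u))) != 0; // holder of the lowest differing bit is smaller
}

int tree_diameter(uint32_t mask, int V, const std::vector<int> &eu,
                  const std::vector<int> &ev) {
  std::vector<std::vector<int> > adj(V);
  for (size_t e = 0; e < eu.size(); ++e)
    if (mask & (uint32_t(1) << e)) {
      adj[eu[e]].push_back(ev[e]);
      adj[ev[e]].push_back(eu[e]);
    }
  int diam = 0;
  std::vector<int> dist(V), queue(V);
  for (int s = 0; s < V; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    int head = 0, tail = 0;
    dist[s] = 0; queue[tail++] = s;
    while (head < tail) {
      int u = queue[head++];
      for (size_t k = 0; k < adj[u].size(); ++k) {
        int w = adj[u][k];
        if (dist[w] < 0) { dist[w] = dist[u] + 1; queue[tail++] = w; }
      }
    }
    for (int v = 0; v < V; ++v) if (dist[v] > diam) diam = dist[v];
  }
  return diam;
}

} // namespace

// Enumerate every labelled spanning tree of the graph as a 32-bit edge mask.
// edges: E x 2 matrix of 0-based vertex indices.
// [[Rcpp::export]]
IntegerVector cpp_enumerate_spanning_trees(IntegerMatrix edges, int V) {
  int E = edges.nrow();
  if (E > 31) stop("at most 31 edges supported");
  EnumCtx ctx;
  ctx.E = E; ctx.V = V;
  ctx.eu.resize(E); ctx.ev.resize(E);
  for (int e = 0; e < E; ++e) { ctx.eu[e] = edges(e, 0); ctx.ev[e] = edges(e, 1); }
  DSU dsu(V);
  ctx.dsu = &dsu;
  std::vector<uint32_t> out;
  ctx.out = &out;
  if (!remainder_connected(ctx, 0, 0)) stop("graph is not connected");
  enum_rec(ctx, 0, 0, 0u);
  IntegerVector res(out.size());
  for (size_t i = 0; i < out.size(); ++i) res[i] = (int)out[i];
  return res;
}

// Partition labelled trees into orbits of the symmetry group and classify
// each orbit.  edge_perm: G x E matrix, 0-based image edge indices.
// face_edges: list of integer vectors of 0-based edge indices per face.
// Returns one row per symmetry class: canonical mask, orbit size, MLD
// (tree diameter), wrapping number (faces carrying face_size-1 tree links).
// [[Rcpp::export]]
DataFrame cpp_classify_trees(IntegerVector masks, IntegerMatrix edge_perm,
                             IntegerMatrix edges, int V, List face_edges) {
  int E = edges.nrow(), G = edge_perm.nrow();
  std::vector<int> eu(E), ev(E);
  for (int e = 0; e < E; ++e) { eu[e] = edges(e, 0); ev[e] = edges(e, 1); }
  std::vector<std::vector<int> > perm(G, std::vector<int>(E));
  for (int g = 0; g < G; ++g)
    for (int e = 0; e < E; ++e) perm[g][e] = edge_perm(g, e);

  // orbit expansion: each unseen tree spawns its full orbit, marked in a
  // bitset over edge masks so later orbit members are skipped in O(1)
  std::vector<uint64_t> seen((uint64_t(1) << E) / 64 + 1, 0);
  std::unordered_map<uint32_t, int> counts;
  counts.reserve(masks.size() / std::max(G, 1) * 2 + 64);
  std::vector<uint32_t> orb(G);
  for (R_xlen_t t = 0; t < masks.size(); ++t) {
    uint32_t m = (uint32_t)masks[t];
    if (seen[m >> 6] & (uint64_t(1) << (m & 63))) continue;
    uint32_t best = m;
    for (int g = 0; g < G; ++g) {
      uint32_t img = 0, mm = m;
      while (mm) {
        int b = __builtin_ctz(mm);
        img |= uint32_t(1) << perm[g][b];
        mm &= mm - 1;
      }
      orb[g] = img;
      seen[img >> 6] |= uint64_t(1) << (img & 63);
      if (lex_less(img, best)) best = img;
    }
    std::sort(orb.begin(), orb.end());
    int osize = (int)(std::unique(orb.begin(), orb.end()) - orb.begin());
    counts[best] = osize;
  }

  int F = face_edges.size();
  std::vector<uint32_t> fmask(F);
  std::vector<int> fsize(F);
  for (int f = 0; f < F; ++f) {
    IntegerVector fe = face_edges[f];
    uint32_t m = 0;
    for (int k = 0; k < fe.size(); ++k) m |= uint32_t(1) << fe[k];
    fmask[f] = m; fsize[f] = fe.size();
  }

  size_t n = counts.size();
  IntegerVector cmask(n), orbit(n), mld(n), np(n);
  size_t i = 0;
  for (std::unordered_map<uint32_t, int>::const_iterator it = counts.begin();
       it != counts.end(); ++it, ++i) {
    uint32_t m = it->first;
    cmask[i] = (int)m;
    orbit[i] = it->second;
    mld[i] = tree_diameter(m, V, eu, ev);
    int w = 0;
    for (int f = 0; f < F; ++f)
      if (__builtin_popcount(m & fmask[f]) == fsize[f] - 1) ++w;
    np[i] = w;
  }
  return DataFrame::create(_["mask"] = cmask, _["orbit_size"] = orbit,
                           _["mld"] = mld, _["np"] = np);
}

// Number of distinct edge subsets forming a simple path through all V
// vertices (each undirected path is found twice by the DFS).
// [[Rcpp::export]]
double cpp_count_hamiltonian_paths(IntegerMatrix edges, int V) {
  int E = edges.nrow();
  std::vector<std::vector<int> > adj(V);
  for (int e = 0; e < E; ++e) {
    adj[edges(e, 0)].push_back(edges(e, 1));
    adj[edges(e, 1)].push_back(edges(e, 0));
  }
  long long count = 0;
  std::vector<bool> used(V, false);
  // iterative DFS with explicit stack of (vertex, next neighbour index)
  std::vector<std::pair<int, size_t> > stack;
  for (int s = 0; s < V; ++s) {
    stack.clear();
    stack.push_back(std::make_pair(s, (size_t)0));
    used[s] = true;
    int depth = 1;
    while (!stack.empty()) {
      std::pair<int, size_t> &top = stack.back();
      if (depth == V) {
        ++count;
        used[top.first] = false; --depth; stack.pop_back();
        continue;
      }
      bool advanced = false;
      while (top.second < adj[top.first].size()) {
        int w = adj[top.first][top.second++];
        if (!used[w]) {
          used[w] = true; ++depth;
          stack.push_back(std::make_pair(w, (size_t)0));
          advanced = true;
          break;
        }
      }
      if (!advanced && depth != V) {
        used[top.first] = false; --depth; stack.pop_back();
      }
    }
  }
  return (double)(count / 2);
}

namespace {

struct FixCtx {
  int V, target;
  std::vector<uint32_t> orbit_mask;
  std::vector<int> orbit_size, suffix_sum;
  std::vector<int> eu, ev;
  long long count;

  bool is_spanning_tree(uint32_t mask) {
    DSU dsu(V);
    int nedges = 0;
    for (size_t e = 0; e < eu.size(); ++e)
      if (mask & (uint32_t(1) << e)) {
        ++nedges;
        if (!dsu.unite(eu[e], ev[e])) return false; // cycle
      }
    if (nedges != V - 1) return false;
    int root = dsu.find(0);
    for (int v = 1; v < V; ++v) if (dsu.find(v) != root) return false;
    return true;
  }

  void rec(size_t i, int got, uint32_t mask) {
    if (got == target) { if (is_spanning_tree(mask)) ++count; return; }
    if (i >= orbit_mask.size() || got + suffix_sum[i] < target) return;
    if (got + orbit_size[i] <= target)
      rec(i + 1, got + orbit_size[i], mask | orbit_mask[i]);
    rec(i + 1, got, mask);
  }
};

} // namespace

// Count labelled spanning trees whose edge set is invariant under the edge
// permutation eperm (0-based).  Intended for non-identity group elements;
// the identity count is the total tree number (matrix-tree theorem).
// [[Rcpp::export]]
double cpp_count_fixed_trees(IntegerVector eperm, IntegerMatrix edges, int V) {
  int E = edges.nrow();
  FixCtx ctx;
  ctx.V = V; ctx.target = V - 1; ctx.count = 0;
  ctx.eu.resize(E); ctx.ev.resize(E);
  for (int e = 0; e < E; ++e) { ctx.eu[e] = edges(e, 0); ctx.ev[e] = edges(e, 1); }
  // cycle decomposition of eperm
  std::vector<bool> seen(E, false);
  for (int e = 0; e < E; ++e) {
    if (seen[e]) continue;
    uint32_t m = 0; int sz = 0, x = e;
    while (!seen[x]) { seen[x] = true; m |= uint32_t(1) << x; ++sz; x = eperm[x]; }
    ctx.orbit_mask.push_back(m);
    ctx.orbit_size.push_back(sz);
  }
  size_t K = ctx.orbit_mask.size();
  ctx.suffix_sum.assign(K + 1, 0);
  for (size_t i = K; i > 0; --i)
    ctx.suffix_sum[i - 1] = ctx.suffix_sum[i] + ctx.orbit_size[i - 1];
  ctx.rec(0, 0, 0u);
  return (double)ctx.count;
}
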