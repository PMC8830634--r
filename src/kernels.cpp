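#include <Rcpp.h>
#include <map>
#include <vector>
#include <array>
#include <functional>
#include <climits>
using namespace Rcpp;

// Shared conventions for the duplication-loss kernels
// ---------------------------------------------------
// Species tree nodes are 1-based ids. `s_lca` is the full node-by-node LCA
// table and `s_depth` the depth of every node (root = 0). Gene trees arrive
// as a children table: row i holds the child ids of gene node i (0 = leaf
// slot), and `g_species` holds the species id of each gene leaf (0 for
// internal nodes). Costs use unit event weights. The cost of a mapping
// includes the "stem" losses from the species root down to the image of the
// gene root, so that a family confined to one subtree of the species tree
// pays one loss at the stem of each bypassed subtree (and none below it).

struct SpTab {
  const IntegerMatrix *lca;
  const IntegerVector *depth;
  int lcaOf(int a, int b) const { return (*lca)(a - 1, b - 1); }
  int depthOf(int a) const { return (*depth)[a - 1]; }
};

// DL cost of a rooted binary gene tree under the LCA mapping.
static int dl_cost_rec(int v, const IntegerMatrix &kids,
                       const IntegerVector &gsp, const SpTab &S, int &cost) {
  int c1 = kids(v - 1, 0), c2 = kids(v - 1, 1);
  if (c1 == 0) return gsp[v - 1];
  int m1 = dl_cost_rec(c1, kids, gsp, S, cost);
  int m2 = dl_cost_rec(c2, kids, gsp, S, cost);
  int mu = S.lcaOf(m1, m2);
  bool dup = (m1 == mu) || (m2 == mu);
  int spec = dup ? 0 : 1;
  cost += (dup ? 1 : 0);
  cost += S.depthOf(m1) - S.depthOf(mu) - spec;
  cost += S.depthOf(m2) - S.depthOf(mu) - spec;
  return mu;
}

// [[Rcpp::export]]
int cpp_dl_cost(IntegerMatrix g_kids, IntegerVector g_species, int g_root,
                IntegerMatrix s_lca, IntegerVector s_depth) {
  SpTab S{&s_lca, &s_depth};
  int cost = 0;
  int mroot = dl_cost_rec(g_root, g_kids, g_species, S, cost);
  cost += S.depthOf(mroot);
  return cost;
}

// Brute-force minimum DL cost over every valid reconciliation mapping:
// each internal gene node may map to any species node that is an ancestor
// of (or equal to) the LCA of its leaf species, subject to the constraint
// that a parent maps at or above both children. Exponential; reference
// oracle for small trees only.
// [[Rcpp::export]]
int cpp_brute_min_cost(IntegerMatrix g_kids, IntegerVector g_species,
                       int g_root, IntegerMatrix s_lca, IntegerVector s_depth,
                       LogicalMatrix s_anc) {
  SpTab S{&s_lca, &s_depth};
  int n = g_kids.nrow(), ns = s_depth.size();
  std::vector<int> post;  // internal nodes, children before parents
  std::vector<int> lcaleaf(n + 1, 0);
  std::function<void(int)> walk = [&](int v) {
    int c1 = g_kids(v - 1, 0), c2 = g_kids(v - 1, 1);
    if (c1 == 0) { lcaleaf[v] = g_species[v - 1]; return; }
    walk(c1); walk(c2);
    lcaleaf[v] = S.lcaOf(lcaleaf[c1], lcaleaf[c2]);
    post.push_back(v);
  };
  walk(g_root);
  int nint = (int)post.size();
  std::vector<std::vector<int>> cand(nint);
  for (int i = 0; i < nint; ++i)
    for (int s = 1; s <= ns; ++s)
      if (s_anc(s - 1, lcaleaf[post[i]] - 1)) cand[i].push_back(s);
  std::vector<int> M(n + 1, 0);
  for (int v = 1; v <= n; ++v)
    if (g_kids(v - 1, 0) == 0) M[v] = g_species[v - 1];
  int best = INT_MAX;
  std::function<void(int)> rec = [&](int i) {
    if (i == nint) {
      int cost = 0;
      for (int j = 0; j < nint; ++j) {
        int v = post[j];
        int m1 = M[g_kids(v - 1, 0)], m2 = M[g_kids(v - 1, 1)], mu = M[v];
        bool spec = (S.lcaOf(m1, m2) == mu) && (m1 != mu) && (m2 != mu);
        cost += spec ? 0 : 1;
        cost += S.depthOf(m1) - S.depthOf(mu) - (spec ? 1 : 0);
        cost += S.depthOf(m2) - S.depthOf(mu) - (spec ? 1 : 0);
      }
      cost += S.depthOf(M[g_root]);
      if (cost < best) best = cost;
      return;
    }
    int v = post[i];
    int c1 = g_kids(v - 1, 0), c2 = g_kids(v - 1, 1);
    for (int s : cand[i]) {
      if (!s_anc(s - 1, M[c1] - 1) || !s_anc(s - 1, M[c2] - 1)) continue;
      M[v] = s;
      rec(i + 1);
    }
  };
  rec(0);
  return best;
}

// ---- exhaustive enumeration of rooted binary shapes over k items --------
// Node references: values < 64 are item indices, values >= 64 are internal
// node indices + 64. Each shape stores its internal nodes and root ref.
struct Shape {
  std::vector<std::array<int, 2>> in;
  int root;
};

static const int REF = 64;

static std::map<int, std::vector<Shape>> shape_cache;

static const std::vector<Shape> &all_shapes(int k) {
  auto it = shape_cache.find(k);
  if (it != shape_cache.end()) return it->second;
  std::vector<Shape> cur;
  cur.push_back(Shape{{}, 0});  // single item 0
  for (int j = 1; j < k; ++j) {
    std::vector<Shape> nxt;
    for (const Shape &s : cur) {
      std::vector<int> refs;
      for (int r = 0; r < j; ++r) refs.push_back(r);
      for (size_t t = 0; t < s.in.size(); ++t) refs.push_back(REF + (int)t);
      for (int r : refs) {
        Shape s2 = s;
        int newref = REF + (int)s2.in.size();
        s2.in.push_back({r, j});
        if (r == s.root) {
          s2.root = newref;
        } else {
          for (auto &nd : s2.in)
            if (&nd != &s2.in.back()) {
              if (nd[0] == r) { nd[0] = newref; break; }
              if (nd[1] == r) { nd[1] = newref; break; }
            }
          s2.root = s.root;
        }
        nxt.push_back(std::move(s2));
      }
    }
    cur = std::move(nxt);
  }
  shape_cache[k] = std::move(cur);
  return shape_cache[k];
}

// [[Rcpp::export]]
int cpp_count_shapes(int k) { return (int)all_shapes(k).size(); }

// Minimum LCA DL cost over every binary refinement of a (possibly
// multifurcating) rooted gene tree: the Cartesian product of all rooted
// binary resolutions of each polytomy is enumerated explicitly. Reference
// oracle for small trees.
// [[Rcpp::export]]
int cpp_min_resolution_cost(List g_children, IntegerVector g_species,
                            int g_root, IntegerMatrix s_lca,
                            IntegerVector s_depth) {
  SpTab S{&s_lca, &s_depth};
  int n = g_children.size();
  std::vector<std::vector<int>> kids(n + 1);
  std::vector<int> polys;
  for (int v = 1; v <= n; ++v) {
    IntegerVector kv = g_children[v - 1];
    kids[v] = std::vector<int>(kv.begin(), kv.end());
    if (kids[v].size() > 2) polys.push_back(v);
  }
  std::vector<int> which_poly(n + 1, -1);
  std::vector<const std::vector<Shape> *> shp(polys.size());
  std::vector<size_t> idx(polys.size(), 0);
  for (size_t i = 0; i < polys.size(); ++i) {
    which_poly[polys[i]] = (int)i;
    shp[i] = &all_shapes((int)kids[polys[i]].size());
  }
  int best = INT_MAX;

  std::function<int(int, int &)> evalNode;
  std::function<int(int, const Shape &, int, int &)> evalRef =
      [&](int v, const Shape &s, int ref, int &cost) -> int {
    if (ref < REF) return evalNode(kids[v][ref], cost);
    const auto &nd = s.in[ref - REF];
    int m1 = evalRef(v, s, nd[0], cost);
    int m2 = evalRef(v, s, nd[1], cost);
    int mu = S.lcaOf(m1, m2);
    bool dup = (m1 == mu) || (m2 == mu);
    int spec = dup ? 0 : 1;
    cost += (dup ? 1 : 0);
    cost += S.depthOf(m1) - S.depthOf(mu) - spec;
    cost += S.depthOf(m2) - S.depthOf(mu) - spec;
    return mu;
  };
  evalNode = [&](int v, int &cost) -> int {
    if (kids[v].empty()) return g_species[v - 1];
    if (kids[v].size() == 2) {
      int m1 = evalNode(kids[v][0], cost);
      int m2 = evalNode(kids[v][1], cost);
      int mu = S.lcaOf(m1, m2);
      bool dup = (m1 == mu) || (m2 == mu);
      int spec = dup ? 0 : 1;
      cost += (dup ? 1 : 0);
      cost += S.depthOf(m1) - S.depthOf(mu) - spec;
      cost += S.depthOf(m2) - S.depthOf(mu) - spec;
      return mu;
    }
    int p = which_poly[v];
    const Shape &s = (*shp[p])[idx[p]];
    return evalRef(v, s, s.root, cost);
  };

  // odometer over per-polytomy shape choices
  bool done = false;
  while (!done) {
    int cost = 0;
    int mroot = evalNode(g_root, cost);
    cost += S.depthOf(mroot);
    if (cost < best) best = cost;
    if (polys.empty()) break;
    size_t i = 0;
    while (i < polys.size()) {
      if (++idx[i] < shp[i]->size()) break;
      idx[i] = 0;
      ++i;
    }
    if (i == polys.size()) done = true;
  }
  return best;
}

// Pairwise p-distances between rows of an integer-coded alignment
// (0 = gap); only columns (from `cols`, 1-based, possibly with repeats)
// where both rows are non-gap enter the denominator. Rows with no shared
// columns get NA.
// [[Rcpp::export]]
NumericMatrix cpp_pdist(IntegerMatrix x, IntegerVector cols) {
  int n = x.nrow(), L = cols.size();
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int shared = 0, diff = 0;
      for (int c = 0; c < L; ++c) {
        int cc = cols[c] - 1;
        int a = x(i, cc), b = x(j, cc);
        if (a != 0 && b != 0) {
          ++shared;
          if (a != b) ++diff;
        }
      }
      double p = shared ? (double)diff / shared : NA_REAL;
      d(i, j) = p;
      d(j, i) = p;
    }
  return d;
}
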