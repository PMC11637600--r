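#include "oracle.h"
#include <random>
#include <algorithm>
#include <climits>

using namespace Rcpp;

// Engine for quartet-guided leaf placement on a backbone tree.
//
// The backbone is an unrooted bifurcating tree held as flat arrays (edges,
// adjacency with degree <= 3, per-node taxon index).  A placement walks a
// centroid decomposition of the backbone: find the centroid of the current
// connected edge subset (the "view"), split the view into the <= 3 parts
// hanging off the centroid, pick orienting leaves per part, resolve the
// quartet {new taxon, a, b, c} with the NJ join criterion, and descend into
// the part whose representative pairs with the new taxon, until a single
// edge remains.
class SnjEngine {
public:
  int nn = 0, ne = 0;          // current node / edge counts
  int nn_cap = 0, ne_cap = 0;
  std::vector<int> e1, e2;     // 0-based endpoints per edge
  std::vector<int> taxon;      // per node: 0 internal, else 1-based taxon id
  std::vector<int> deg, nbr, eid;  // adjacency, 3 slots per node

  DistanceOracle* oracle = nullptr;
  int samples = 1, orienting = 1;
  std::mt19937 rng;

  long long fallbacks = 0;

  SnjEngine(int nn_cap_in, int ne_cap_in) {
    nn_cap = std::max(nn_cap_in, 4);
    ne_cap = std::max(ne_cap_in, 3);
    e1.resize(ne_cap); e2.resize(ne_cap);
    taxon.assign(nn_cap, 0);
    deg.assign(nn_cap, 0);
    nbr.assign(3 * static_cast<size_t>(nn_cap), -1);
    eid.assign(3 * static_cast<size_t>(nn_cap), -1);
    stamp_edge.assign(ne_cap, 0);
    stamp_node.assign(nn_cap, 0);
    parent.assign(nn_cap, -1);
    leafcnt.assign(nn_cap, 0);
    viewdeg.assign(nn_cap, 0);
  }

  void init_backbone(const IntegerMatrix& edge, const IntegerVector& tax,
                     int n_nodes) {
    nn = n_nodes;
    ne = edge.nrow();
    for (int v = 0; v < n_nodes; ++v) taxon[v] = tax[v];
    for (int e = 0; e < ne; ++e) {
      int a = edge(e, 0) - 1, b = edge(e, 1) - 1;
      e1[e] = a; e2[e] = b;
      add_adj(a, b, e);
      add_adj(b, a, e);
    }
  }

  void add_adj(int v, int w, int e) {
    if (deg[v] >= 3) stop("node degree exceeds 3");
    nbr[3 * static_cast<size_t>(v) + deg[v]] = w;
    eid[3 * static_cast<size_t>(v) + deg[v]] = e;
    ++deg[v];
  }

  void replace_adj(int v, int old_w, int new_w, int new_e) {
    for (int t = 0; t < deg[v]; ++t) {
      size_t s = 3 * static_cast<size_t>(v) + t;
      if (nbr[s] == old_w) { nbr[s] = new_w; eid[s] = new_e; return; }
    }
    stop("internal error: adjacency entry not found");
  }

  // subdivide edge e with new internal node, attach new leaf for taxon t
  void insert(int e, int t) {
    int u = e1[e], v = e2[e];
    int w = nn++;
    int x = nn++;
    taxon[w] = 0;
    taxon[x] = t;
    e2[e] = w;                       // edge e becomes (u, w)
    int ev = ne; e1[ne] = w; e2[ne] = v; ++ne;
    int ex = ne; e1[ne] = w; e2[ne] = x; ++ne;
    replace_adj(u, v, w, e);
    replace_adj(v, u, w, ev);
    add_adj(w, u, e);
    add_adj(w, v, ev);
    add_adj(w, x, ex);
    add_adj(x, w, ex);
  }

  // centroid of the connected view (edge-id list); marks the view with a
  // fresh token as a side effect.  Returns -1 if the view is disconnected
  // (checked only when `check` is true).
  int centroid(const std::vector<int>& view, bool check) {
    int vtok = ++token;
    for (int e : view) stamp_edge[e] = vtok;
    // view nodes + view degrees
    vnodes.clear();
    for (int e : view) {
      for (int v : {e1[e], e2[e]}) {
        if (stamp_node[v] != vtok) {
          stamp_node[v] = vtok;
          viewdeg[v] = 0;
          vnodes.push_back(v);
        }
        ++viewdeg[v];
      }
    }
    int L = 0;
    for (int v : vnodes) if (taxon[v] > 0) ++L;
    // DFS from vnodes[0] over view edges, preorder into `order`
    order.clear();
    stack_buf.clear();
    int root = vnodes[0];
    parent[root] = -1;
    int dtok = ++token;
    stamp_node[root] = dtok;
    stack_buf.push_back(root);
    while (!stack_buf.empty()) {
      int v = stack_buf.back(); stack_buf.pop_back();
      order.push_back(v);
      leafcnt[v] = (taxon[v] > 0) ? 1 : 0;
      for (int t = 0; t < deg[v]; ++t) {
        size_t s = 3 * static_cast<size_t>(v) + t;
        if (stamp_edge[eid[s]] != vtok) continue;
        int w = nbr[s];
        if (stamp_node[w] == dtok) continue;
        stamp_node[w] = dtok;
        parent[w] = v;
        stack_buf.push_back(w);
      }
    }
    if (check && order.size() != vnodes.size()) return -1;
    for (size_t i = order.size(); i-- > 1; ) {
      int v = order[i];
      leafcnt[parent[v]] += leafcnt[v];
    }
    // re-mark view nodes for viewdeg lookup (stamp_node got reused); viewdeg
    // entries are still valid for nodes in `vnodes`
    int best = -1, best_max = INT_MAX;
    for (int v : vnodes) {
      if (viewdeg[v] < 2) continue;
      int mx = L - leafcnt[v];
      for (int t = 0; t < deg[v]; ++t) {
        size_t s = 3 * static_cast<size_t>(v) + t;
        if (stamp_edge[eid[s]] != vtok) continue;
        int w = nbr[s];
        if (parent[w] == v && stamp_node[w] == dtok)
          mx = std::max(mx, leafcnt[w]);
      }
      if (mx < best_max || (mx == best_max && v < best)) {
        best = v;
        best_max = mx;
      }
    }
    view_token = vtok;
    return best;
  }

  // split the marked view (token from the last centroid() call) at node c
  // into its three backbone directions, ordered by neighbor node id.
  // Fills part_edges / part_leaves / dir_nbr / dir_edge.
  void split_at(int c) {
    int idx[3] = {0, 1, 2};
    int w0[3], ed0[3];
    if (deg[c] != 3) stop("internal error: centroid is not an internal node");
    for (int t = 0; t < 3; ++t) {
      size_t s = 3 * static_cast<size_t>(c) + t;
      w0[t] = nbr[s];
      ed0[t] = eid[s];
    }
    std::sort(idx, idx + 3, [&](int a, int b) { return w0[a] < w0[b]; });
    for (int p = 0; p < 3; ++p) {
      dir_nbr[p] = w0[idx[p]];
      dir_edge[p] = ed0[idx[p]];
      part_edges[p].clear();
      part_leaves[p].clear();
      if (stamp_edge[dir_edge[p]] != view_token) continue;  // empty part
      // DFS from dir_nbr avoiding c over view edges
      int dtok = ++token;
      stamp_node[c] = dtok;
      stamp_node[dir_nbr[p]] = dtok;
      stack_buf.clear();
      stack_buf.push_back(dir_nbr[p]);
      part_edges[p].push_back(dir_edge[p]);
      if (taxon[dir_nbr[p]] > 0) part_leaves[p].push_back(dir_nbr[p]);
      while (!stack_buf.empty()) {
        int v = stack_buf.back(); stack_buf.pop_back();
        for (int t = 0; t < deg[v]; ++t) {
          size_t s = 3 * static_cast<size_t>(v) + t;
          if (stamp_edge[eid[s]] != view_token) continue;
          int w = nbr[s];
          if (stamp_node[w] == dtok) continue;
          stamp_node[w] = dtok;
          part_edges[p].push_back(eid[s]);
          if (taxon[w] > 0) part_leaves[p].push_back(w);
          stack_buf.push_back(w);
        }
      }
    }
  }

  // taxa on the backbone side of c through neighbor w (covering component)
  void covering_taxa(int c, int w, std::vector<int>& out) {
    out.clear();
    int dtok = ++token;
    stamp_node[c] = dtok;
    stamp_node[w] = dtok;
    stack_buf.clear();
    stack_buf.push_back(w);
    if (taxon[w] > 0) out.push_back(w);
    while (!stack_buf.empty()) {
      int v = stack_buf.back(); stack_buf.pop_back();
      for (int t = 0; t < deg[v]; ++t) {
        int u = nbr[3 * static_cast<size_t>(v) + t];
        if (stamp_node[u] == dtok) continue;
        stamp_node[u] = dtok;
        if (taxon[u] > 0) out.push_back(u);
        stack_buf.push_back(u);
      }
    }
  }

  // place taxon t; returns 0-based edge id, sets `rounds`
  int place(int t, int& rounds, bool& fallback) {
    view.clear();
    for (int e = 0; e < ne; ++e) view.push_back(e);
    rounds = 0;
    fallback = false;
    while (view.size() > 1) {
      ++rounds;
      int c = centroid(view, false);
      split_at(c);
      // orienting representatives per part
      for (int p = 0; p < 3; ++p) {
        std::vector<int>* cands = &part_leaves[p];
        if (cands->empty()) {
          covering_taxa(c, dir_nbr[p], cover_buf);
          cands = &cover_buf;
        }
        if (cands->empty())
          stop("internal error: no taxa on one side of the centroid");
        int sz = static_cast<int>(cands->size());
        int k = std::min(samples, sz);
        // partial Fisher-Yates
        for (int i = 0; i < k; ++i) {
          int j = i + static_cast<int>(rng() % static_cast<uint32_t>(sz - i));
          std::swap((*cands)[i], (*cands)[j]);
        }
        picked.clear();
        for (int i = 0; i < k; ++i) {
          int node = (*cands)[i];
          double d = oracle->query(t - 1, taxon[node] - 1);
          picked.push_back({d, taxon[node]});
        }
        std::sort(picked.begin(), picked.end());
        int o = std::min(orienting, k);
        reps[p].clear();
        for (int i = 0; i < o; ++i) reps[p].push_back(picked[i].second);
      }
      // averaged 4x4 quartet matrix over {t, A, B, C}
      double a4[4][4] = {{0}};
      for (int p = 0; p < 3; ++p) {
        double s = 0.0;
        for (int x : reps[p]) s += oracle->query(t - 1, x - 1);
        a4[0][p + 1] = a4[p + 1][0] = s / reps[p].size();
      }
      for (int p = 0; p < 3; ++p) {
        for (int q = p + 1; q < 3; ++q) {
          double s = 0.0;
          for (int x : reps[p])
            for (int y : reps[q]) s += oracle->query(x - 1, y - 1);
          a4[p + 1][q + 1] = a4[q + 1][p + 1] =
            s / (static_cast<double>(reps[p].size()) * reps[q].size());
        }
      }
      // NJ join criterion on 4 taxa, lexicographic tie rule
      double u4[4];
      for (int i = 0; i < 4; ++i)
        u4[i] = (a4[i][0] + a4[i][1] + a4[i][2] + a4[i][3]) / 2.0;
      int bi = -1, bj = -1;
      double bq = R_PosInf;
      for (int i = 0; i < 4; ++i) {
        for (int j = i + 1; j < 4; ++j) {
          double q = a4[i][j] - u4[i] - u4[j];
          if (q < bq) { bq = q; bi = i; bj = j; }
        }
      }
      int partner;
      if (bi == 0) partner = bj;
      else partner = 6 - bi - bj;     // the index not in {bi, bj}, != 0
      int p = partner - 1;
      if (part_edges[p].empty()) {
        // quartet points past the view boundary: stop at the backbone edge
        // leaving the centroid in that direction
        ++fallbacks;
        fallback = true;
        return dir_edge[p];
      }
      view.swap(part_edges[p]);
    }
    return view[0];
  }

private:
  std::vector<int> stamp_edge, stamp_node;
  std::vector<int> parent, leafcnt, viewdeg;
  std::vector<int> vnodes, order, stack_buf;
  std::vector<int> view, cover_buf;
  std::vector<int> part_edges[3];
  std::vector<int> part_leaves[3];
  std::vector<std::pair<double, int>> picked;
  std::vector<int> reps[3];
  int dir_nbr[3] = {0, 0, 0}, dir_edge[3] = {0, 0, 0};
  int token = 0, view_token = 0;
};

// [[Rcpp::export(name = ".snj_centroid_cpp")]]
List snj_centroid_cpp(IntegerMatrix edge, int n_nodes, IntegerVector tax,
                      IntegerVector view) {
  SnjEngine eng(n_nodes, edge.nrow());
  eng.init_backbone(edge, tax, n_nodes);
  std::vector<int> v(view.size());
  for (int i = 0; i < view.size(); ++i) v[i] = view[i] - 1;
  int c = eng.centroid(v, true);
  return List::create(_["node"] = c + 1, _["connected"] = (c >= 0));
}

// [[Rcpp::export(name = ".snj_place_cpp")]]
List snj_place_cpp(IntegerMatrix edge, int n_nodes, IntegerVector tax,
                   int new_taxon, SEXP oracle_xp, int samples, int orienting,
                   int seed) {
  XPtr<DistanceOracle> op(oracle_xp);
  SnjEngine eng(n_nodes, edge.nrow());
  eng.init_backbone(edge, tax, n_nodes);
  eng.oracle = op.get();
  eng.samples = samples;
  eng.orienting = orienting;
  eng.rng.seed(static_cast<uint32_t>(seed));
  int rounds = 0;
  bool fb = false;
  int e = eng.place(new_taxon, rounds, fb);
  return List::create(_["edge"] = e + 1, _["rounds"] = rounds,
                      _["fallback"] = fb);
}

// Insert all taxa in `order` (1-based taxon ids) into the backbone, one
// placement + edge subdivision per taxon.
// [[Rcpp::export(name = ".snj_build_cpp")]]
List snj_build_cpp(IntegerMatrix edge, int n_nodes, IntegerVector tax,
                   int n_final, IntegerVector order, SEXP oracle_xp,
                   int samples, int orienting, IntegerVector seeds) {
  XPtr<DistanceOracle> op(oracle_xp);
  SnjEngine eng(2 * n_final - 2, 2 * n_final - 3);
  eng.init_backbone(edge, tax, n_nodes);
  eng.oracle = op.get();
  eng.samples = samples;
  eng.orienting = orienting;
  int ni = order.size();
  IntegerVector chosen(ni), rounds_out(ni);
  for (int i = 0; i < ni; ++i) {
    eng.rng.seed(static_cast<uint32_t>(seeds[i]));
    int rounds = 0;
    bool fb = false;
    int e = eng.place(order[i], rounds, fb);
    eng.insert(e, order[i]);
    chosen[i] = e + 1;
    rounds_out[i] = rounds;
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  IntegerMatrix out_edge(eng.ne, 2);
  for (int e = 0; e < eng.ne; ++e) {
    out_edge(e, 0) = eng.e1[e] + 1;
    out_edge(e, 1) = eng.e2[e] + 1;
  }
  IntegerVector out_tax(eng.nn);
  for (int v = 0; v < eng.nn; ++v) out_tax[v] = eng.taxon[v];
  return List::create(
    _["edge"] = out_edge,
    _["taxon_of_node"] = out_tax,
    _["n_nodes"] = eng.nn,
    _["chosen"] = chosen,
    _["rounds"] = rounds_out,
    _["fallbacks"] = static_cast<double>(eng.fallbacks));
}
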