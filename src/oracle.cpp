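#include "oracle.h"
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static inline uint64_t pair_key(int i, int j) {
  if (i > j) std::swap(i, j);
  return (static_cast<uint64_t>(i) << 32) | static_cast<uint32_t>(j);
}

// splitmix64: used to derive a deterministic per-pair perturbation so the
// noise does not depend on query order
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

double DistanceOracle::tree_dist(int i, int j) const {
  int u = tip_node[i], v = tip_node[j];
  if (u == v) return 0.0;
  double d = wdepth[u] + wdepth[v];
  // lift to equal depth, then jointly
  int a = u, b = v;
  if (idepth[a] < idepth[b]) std::swap(a, b);
  int diff = idepth[a] - idepth[b];
  for (int k = 0; diff; ++k, diff >>= 1)
    if (diff & 1) a = up[k * nn + a];
  if (a != b) {
    for (int k = LOG - 1; k >= 0; --k) {
      if (up[k * nn + a] != up[k * nn + b]) {
        a = up[k * nn + a];
        b = up[k * nn + b];
      }
    }
    a = up[a];  // k = 0 row
  }
  return d - 2.0 * wdepth[a];
}

double DistanceOracle::compute(int i, int j) {
  double d = 0.0;
  switch (backing) {
  case MATRIX:
    d = mat[static_cast<size_t>(i) * n + j];
    break;
  case SEQUENCES: {
    const int* si = &seq[static_cast<size_t>(i) * m];
    const int* sj = &seq[static_cast<size_t>(j) * m];
    long comparable = 0, mismatch = 0;
    for (int s = 0; s < m; ++s) {
      int a = si[s], b = sj[s];
      if (a > 0 && b > 0) {
        ++comparable;
        mismatch += (a != b);
      }
    }
    if (comparable == 0)
      stop("no comparable sites between taxa '%s' and '%s'", taxa[i], taxa[j]);
    double p = static_cast<double>(mismatch) / comparable;
    if (!jc) {
      d = p;
    } else {
      double arg = 1.0 - (4.0 / 3.0) * p;
      if (arg <= 0.0) {
        d = cap;
        ++n_saturated;
      } else {
        d = -0.75 * std::log(arg);
        if (d > cap) { d = cap; ++n_saturated; }
      }
    }
    break;
  }
  case TREE:
    d = tree_dist(i, j);
    break;
  }
  if (noise > 0.0) {
    uint64_t h = splitmix64(pair_key(i, j) ^ noise_seed);
    double u01 = (h >> 11) * (1.0 / 9007199254740992.0);  // [0, 1)
    d += noise * (2.0 * u01 - 1.0);
  }
  return d;
}

double DistanceOracle::query(int i, int j) {
  if (i == j) return 0.0;
  uint64_t key = pair_key(i, j);
  auto it = cache.find(key);
  if (it != cache.end()) return it->second;
  double d = compute(i, j);
  cache.emplace(key, d);
  ++n_distinct;
  return d;
}

static DistanceOracle* get_oracle(SEXP xp) {
  XPtr<DistanceOracle> p(xp);
  return p.get();
}

// [[Rcpp::export(name = ".oracle_matrix_cpp")]]
SEXP oracle_matrix_cpp(NumericMatrix D, CharacterVector taxa,
                       double noise, int noise_seed) {
  DistanceOracle* o = new DistanceOracle();
  o->backing = DistanceOracle::MATRIX;
  o->n = taxa.size();
  o->taxa = as<std::vector<std::string>>(taxa);
  o->mat.assign(o->n * static_cast<size_t>(o->n), 0.0);
  for (int i = 0; i < o->n; ++i)
    for (int j = 0; j < o->n; ++j)
      o->mat[static_cast<size_t>(i) * o->n + j] = D(i, j);
  o->noise = noise;
  o->noise_seed = static_cast<uint64_t>(noise_seed);
  return XPtr<DistanceOracle>(o, true);
}

// seq: m x n integer matrix, codes 0 (non-comparable) or 1..4
// [[Rcpp::export(name = ".oracle_sequences_cpp")]]
SEXP oracle_sequences_cpp(IntegerMatrix seqm, CharacterVector taxa,
                          bool jc, double cap, double noise, int noise_seed) {
  DistanceOracle* o = new DistanceOracle();
  o->backing = DistanceOracle::SEQUENCES;
  o->n = taxa.size();
  o->m = seqm.nrow();
  o->taxa = as<std::vector<std::string>>(taxa);
  o->seq.assign(seqm.begin(), seqm.end());  // column-major: taxon-contiguous
  o->jc = jc;
  o->cap = cap;
  o->noise = noise;
  o->noise_seed = static_cast<uint64_t>(noise_seed);
  return XPtr<DistanceOracle>(o, true);
}

// edge: ne x 2 (1-based node ids), lengths per edge, tip_nodes (1-based) per taxon
// [[Rcpp::export(name = ".oracle_tree_cpp")]]
SEXP oracle_tree_cpp(IntegerMatrix edge, NumericVector lengths,
                     IntegerVector tip_nodes, CharacterVector taxa,
                     int n_nodes, double noise, int noise_seed) {
  DistanceOracle* o = new DistanceOracle();
  o->backing = DistanceOracle::TREE;
  o->n = taxa.size();
  o->taxa = as<std::vector<std::string>>(taxa);
  o->nn = n_nodes;
  int ne = edge.nrow();

  // adjacency
  std::vector<int> deg(n_nodes, 0);
  for (int e = 0; e < ne; ++e) {
    ++deg[edge(e, 0) - 1];
    ++deg[edge(e, 1) - 1];
  }
  std::vector<int> start(n_nodes + 1, 0);
  for (int v = 0; v < n_nodes; ++v) start[v + 1] = start[v] + deg[v];
  std::vector<int> adj_v(2 * ne), adj_w(2 * ne);
  {
    std::vector<int> pos(start.begin(), start.end() - 1);
    for (int e = 0; e < ne; ++e) {
      int a = edge(e, 0) - 1, b = edge(e, 1) - 1;
      adj_v[pos[a]] = b; adj_w[pos[a]] = e; ++pos[a];
      adj_v[pos[b]] = a; adj_w[pos[b]] = e; ++pos[b];
    }
  }

  o->LOG = 1;
  while ((1 << o->LOG) < n_nodes) ++o->LOG;
  o->up.assign(static_cast<size_t>(o->LOG) * n_nodes, 0);
  o->wdepth.assign(n_nodes, 0.0);
  o->idepth.assign(n_nodes, 0);

  // iterative DFS from node 0
  std::vector<int> stack;
  std::vector<char> seen(n_nodes, 0);
  stack.push_back(0);
  seen[0] = 1;
  o->up[0] = 0;
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    for (int t = start[v]; t < start[v + 1]; ++t) {
      int w = adj_v[t];
      if (!seen[w]) {
        seen[w] = 1;
        o->up[w] = v;
        o->wdepth[w] = o->wdepth[v] + lengths[adj_w[t]];
        o->idepth[w] = o->idepth[v] + 1;
        stack.push_back(w);
      }
    }
  }
  for (int k = 1; k < o->LOG; ++k)
    for (int v = 0; v < n_nodes; ++v)
      o->up[static_cast<size_t>(k) * n_nodes + v] =
        o->up[static_cast<size_t>(k - 1) * n_nodes +
              o->up[static_cast<size_t>(k - 1) * n_nodes + v]];

  o->tip_node.resize(o->n);
  for (int i = 0; i < o->n; ++i) o->tip_node[i] = tip_nodes[i] - 1;
  o->noise = noise;
  o->noise_seed = static_cast<uint64_t>(noise_seed);
  return XPtr<DistanceOracle>(o, true);
}

// [[Rcpp::export(name = ".oracle_query_cpp")]]
NumericVector oracle_query_cpp(SEXP xp, IntegerVector i, IntegerVector j) {
  DistanceOracle* o = get_oracle(xp);
  int k = i.size();
  NumericVector out(k);
  for (int t = 0; t < k; ++t) {
    int a = i[t] - 1, b = j[t] - 1;
    if (a < 0 || a >= o->n || b < 0 || b >= o->n)
      stop("taxon index out of range");
    out[t] = o->query(a, b);
  }
  return out;
}

// Full symmetric distance block among a subset of taxa (each distinct pair
// goes through the memoizing query path).
// [[Rcpp::export(name = ".oracle_block_cpp")]]
NumericMatrix oracle_block_cpp(SEXP xp, IntegerVector idx) {
  DistanceOracle* o = get_oracle(xp);
  int k = idx.size();
  NumericMatrix out(k, k);
  for (int a = 0; a < k; ++a) {
    for (int b = a + 1; b < k; ++b) {
      double d = o->query(idx[a] - 1, idx[b] - 1);
      out(a, b) = d;
      out(b, a) = d;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".oracle_stats_cpp")]]
List oracle_stats_cpp(SEXP xp) {
  DistanceOracle* o = get_oracle(xp);
  return List::create(
    _["n_taxa"] = o->n,
    _["distinct_queries"] = static_cast<double>(o->n_distinct),
    _["saturated"] = static_cast<double>(o->n_saturated));
}

// [[Rcpp::export(name = ".oracle_taxa_cpp")]]
CharacterVector oracle_taxa_cpp(SEXP xp) {
  DistanceOracle* o = get_oracle(xp);
  return wrap(o->taxa);
}
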