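#ifndef SPARSENJ_ORACLE_H
#define SPARSENJ_ORACLE_H

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>

// Memoizing pairwise-distance oracle.  A query for an unordered pair {i, j}
// is computed once from the backing source, cached, and counted; repeated
// queries hit the cache and do not increment the distinct-query counter.
class DistanceOracle {
public:
  enum Backing { MATRIX, SEQUENCES, TREE };

  Backing backing;
  int n = 0;                       // number of taxa
  std::vector<std::string> taxa;

  // MATRIX backing: dense n x n (row-major not needed; symmetric)
  std::vector<double> mat;

  // SEQUENCES backing: codes 0 (non-ACGT) / 1..4, column-major m x n so that
  // a taxon's sites are contiguous
  std::vector<int> seq;
  int m = 0;
  bool jc = true;          // Jukes-Cantor transform vs raw mismatch proportion
  double cap = 10.0;       // saturation cap (expected substitutions/site)

  // TREE backing: weighted tree path lengths via binary-lifting LCA
  int nn = 0;                      // number of tree nodes
  std::vector<int> tip_node;       // taxon index -> node (0-based)
  std::vector<double> wdepth;      // branch-length depth from root
  std::vector<int> idepth;         // integer depth
  std::vector<int> up;             // LOG * nn ancestor table
  int LOG = 1;

  // optional additive perturbation, deterministic per unordered pair
  double noise = 0.0;
  uint64_t noise_seed = 0;

  std::unordered_map<uint64_t, double> cache;
  uint64_t n_distinct = 0;
  uint64_t n_saturated = 0;

  double query(int i, int j);      // 0-based taxon indices
private:
  double compute(int i, int j);
  double tree_dist(int i, int j) const;
};

#endif
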