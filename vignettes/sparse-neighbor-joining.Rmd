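---
title: "Sparse Neighbor Joining: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse Neighbor Joining: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsenj)
```

## The problem and the cost model

For a dataset of n taxa and m aligned sites, distance-based tree inference
splits into two costs: computing pairwise distances, O(f(m)·n²) with f(m) the
per-pair cost, and the tree-building recursion itself. When m > n — the
common situation with modern alignments — the distance matrix is the
bottleneck, and none of the classical accelerations of Neighbor Joining
remove it, because they all still consume the full matrix.

`sparsenj` therefore treats *the number of distinct pairwise distances ever
computed* as the primary cost. Every inference runs against a
`distance_oracle`: queries are computed on demand from the backing source
(aligned sequences, a precomputed matrix, or a weighted tree), memoized, and
counted. The counter is exact — repeated queries of the same unordered pair
cost nothing and count once — so `oracle_stats()` reports precisely how much
of the n(n−1)/2 matrix a run touched.

## The inference procedure

The backbone is built by canonical NJ (`neighbor_joining()`): join the pair
minimising `D_ij − u_i − u_j`, `u_i = Σ_{j≠i} D_ij/(n−2)`, reduce with
`D_(ij),k = (D_ik + D_jk − D_ij)/2`, ties broken by the lexicographically
smallest active pair so results are deterministic. Branch lengths are never
stored: placement needs only the topology, and lengths can be fit afterwards
by any standard optimizer if needed.

Each remaining taxon ℓ is inserted by `place_leaf()`:

1. Start with the whole backbone as the current *view* (a connected edge
   subset).
2. Find the view's **centroid** (`find_centroid()`): the internal node
   minimising the largest leaf count among the components its removal
   creates; Jordan's argument guarantees every component holds at most
   ⌈L/2⌉ of the view's L leaves. Remaining ties go to the smallest node id.
3. **Decompose** at the centroid into the three parts along its backbone
   directions. A part with edges but no leaves, or a direction the view does
   not extend into, is represented by the *covering component* — the full
   backbone component on that side of the centroid — from which orienting
   leaves are then drawn; every side of an internal node contains at least
   one leaf, so this never fails.
4. Sample candidate leaves per part, keep the closest to ℓ as **orienting
   leaves**, build the 4×4 matrix over {ℓ, A, B, C} from averaged oracle
   distances, and resolve the quartet by the NJ join criterion. The part
   whose representative pairs with ℓ becomes the next view.
5. Stop when the view is a single edge; subdivide it (`insert_leaf()`).

Because each step at least halves the remaining leaves, an insertion uses at
most ⌈log₂(2k−3)⌉ + 2 quartet rounds (asserted as a property test), giving
the O(n log n) / O(n log² n) total query bounds of the basic and enhanced
variants.

### Correctness inside the convergence radius

If every oracle answer deviates from the true path length by less than half
the shortest branch λ(T)/2, NJ recovers every quartet and the initial
backbone exactly, and a short overlap argument shows each averaged quartet
then points ℓ into the component containing its true edge; by induction the
exact true topology is returned. The test suite exercises this both
noiselessly and with per-pair uniform noise at 0.45·λ(T). With Jukes–Cantor
distance estimates the error of every entry vanishes in probability as
m → ∞, so recovery of the true topology is attained with probability tending
to one — the finite-m accuracy trend is measured, not assumed (see
"Calibration" below).

## Tunable parameters

All defaults live in `snj_config()` and resolve against the dataset size n:

| parameter | basic | enhanced | meaning |
|---|---|---|---|
| `k0` | 4 | ⌈√(n·log₂ n)⌉, clamped to [4, n] | initial backbone leaves; dense NJ on k0 taxa costs k0(k0−1)/2 ≈ n·log₂ n/2 queries, matching the insertion budget |
| `samples_per_subtree` | 1 | ⌈log₂ n⌉ | candidates drawn (without replacement, truncated to the part size) per centroid part per round |
| `orienting_per_subtree` | 1 | 3 (clamped to the sample count) | closest candidates kept; quartet entries are means over these sets |
| `seed` | — | — | master seed; backbone choice, insertion order and per-insertion sampling run on three derived substreams, so each component is reproducible in isolation |

All logarithms in these counts are base-2 with ceiling; any fixed base only
changes constants, and base 2 matches the halving recursion. Distances
default to Jukes–Cantor, `−(3/4)·log(1 − (4/3)p)` over comparable sites with
pairwise deletion of gaps/ambiguity codes; `p ≥ 3/4` is undefined under the
model and is capped (default 10 expected substitutions/site, flagged) so a
single saturated pair cannot abort a run. The raw mismatch proportion
(`distance = "hamming"`) is available for speed or for model-free use.

## The simulator and what passing tests mean

`simulate_dataset()` reproduces the standard synthetic protocol: a topology
grown by uniformly merging random component pairs, i.i.d. exponential branch
lengths with mean 1e-3 expected substitutions/site, and exact Jukes–Cantor
site evolution (uniform root sequence, per-edge substitution probability
(3/4)(1−e^{−4t/3}); the model is reversible and the root choice is
arbitrary, which a test verifies distributionally). The mean-1e-3 regime is
deliberately hard: trees are short and many internal branches carry less
than one expected substitution over realistic m.

What the simulator does *not* emulate: rate heterogeneity across sites or
lineages, indels and alignment error, non-uniform base composition, and any
non-JC substitution process. Passing tests therefore demonstrate
correctness of the algorithms and their behaviour under the stated model —
not robustness to model misspecification on real alignments.

## Numerical and degenerate-input choices

* Centroid ties: minimise the maximum component leaf count, then smallest
  node id — determinism for testing, and the balanced choice keeps the
  recursion shallow.
* Quartets with all-equal distances join the lexicographically first pair;
  all tie rules are exercised by tests on degenerate matrices.
* If a quartet points into an *empty* part (possible only with noisy
  distances — the quartet claims ℓ lies beyond the current view), placement
  terminates on the backbone edge leaving the centroid in that direction:
  the nearest edge consistent with the quartet's verdict.
* A 3-leaf backbone is handled as a single quartet round over its three
  edges.
* Sequence pairs with zero comparable sites are an error, not a silent 0.
* PHYLIP matrices: square and lower-triangular dialects auto-detected;
  asymmetries ≤ 1e-9 are averaged away with a warning, larger ones refused.
* Newick output is canonicalised (children ordered by smallest descendant
  label, written from the internal neighbour of the first label) so
  write → read → write is byte-identical; metacharacter labels are refused.

## Problem sizes used by the checks

The test suite validates the metrics exhaustively on 5–6-leaf tree pairs
and on random 7–8-leaf pairs against brute-force oracles; exact recovery is
checked on hundreds of random trees up to n = 200; the sparsity measurement
runs once at n = 23,331 over an additive oracle; and the sequence-based
accuracy measurement uses n = 1000, m = 20,000 over three seeds, with a
reduced n = 150 smoke version in the unit tests. The split-matrix machinery
behind RF/transfer is O(n²) and is used up to n ≈ 1000, which the accuracy
experiments need; the 23k-taxon run only counts queries and needs no
metrics.

## Calibration results and known limitations

* Measured at n = 23,331 (enhanced defaults, additive oracle), the method
  queries ≈ 8.2M distinct pairs, a fraction ≈ 0.030 of the 272M total. The
  per-insertion budget of three parts × ⌈log₂ n⌉ candidates over ~log₂ n
  rounds makes ≈ 3·log₂²n fresh queries per insertion unavoidable; a
  substantially smaller count would require sampling fewer candidates than
  the enhanced configuration specifies.
* At n = 50 with mean-1e-3 branches, the shortest branch (~1e-5) lies far
  below the Jukes–Cantor estimator noise even at m = 32,000 (~6e-4), so
  *exact* recovery is rare for any distance method in this regime — dense NJ
  achieves RF = 0 in only about half the replicates — although mean RF
  falls monotonically with m (0.70 → 0.31 → 0.12 → 0.02 across m = 500,
  2000, 8000, 32,000 in our runs).
* Transfer distance is the headline accuracy metric because RF saturates:
  moving one leaf across a caterpillar flips almost every bipartition (RF
  near 1) while the transfer distance stays small; a constructed example in
  the tests demonstrates the contrast. Transfer normalisation follows the
  smaller-side convention and averages over the n−3 non-trivial reference
  edges (pendant edges would contribute identical zeros).
* Insertion errors compound: `insertion_error_audit()` isolates them by
  relocating each taxon to its reference position after recording the
  displacement of the chosen edge, which is the right tool for judging the
  placement step itself rather than the full pipeline.
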