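Package: sparsenj
Title: Sparse Neighbor Joining for Large Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distance-based phylogenetic inference without a dense distance
    matrix. Builds an unrooted bifurcating topology by inserting taxa one at a
    time into a backbone tree, locating each insertion edge through a centroid
    decomposition of the backbone and quartet queries against a memoizing
    pairwise-distance oracle, so that only O(n log n) to O(n log^2 n) of the
    n(n-1)/2 distances are ever computed. Includes the canonical Neighbor
    Joining baseline, Jukes-Cantor distance estimation from aligned DNA, a
    synthetic-data simulator (random merge topologies, exponential branch
    lengths, Jukes-Cantor sequence evolution), and Robinson-Foulds, transfer
    and quartet tree-comparison metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
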