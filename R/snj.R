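#' Configuration for sparse incremental inference
#'
#' Controls the two variants of the sparse method.  In `basic` mode the
#' backbone starts from 4 random taxa and a single uniformly sampled
#' orienting leaf represents each centroid component.  In `enhanced` mode the
#' backbone starts from `k0 = ceiling(sqrt(n * log2(n)))` taxa (so the dense
#' initialisation costs about `n log2 n / 2` distance queries), each centroid
#' component contributes `ceiling(log2(n))` sampled candidate leaves of which
#' the 3 closest to the new taxon are kept, and quartets are formed from
#' averaged distances over those orienting sets.
#'
#' @param mode `"enhanced"` (default) or `"basic"`.
#' @param k0 initial backbone leaf count, or `"auto"` (basic: 4; enhanced:
#'   `ceiling(sqrt(n * log2(n)))`, clamped to `[4, n]`).
#' @param samples_per_subtree candidate leaves sampled per centroid
#'   component, or `"auto"` (basic: 1; enhanced: `ceiling(log2(n))`).
#' @param orienting_per_subtree orienting leaves kept per component (basic
#'   default 1, enhanced default 3; never more than the sampled count).
#' @param seed master seed; backbone choice, insertion order and
#'   per-insertion sampling run on named substreams derived from it.
#' @return An object of class `"snj_config"`.
#' @export
snj_config <- function(mode = c("enhanced", "basic"), k0 = "auto",
                       samples_per_subtree = "auto",
                       orienting_per_subtree = NULL, seed = 1L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, k0 = k0,
                 samples_per_subtree = samples_per_subtree,
                 orienting_per_subtree = orienting_per_subtree,
                 seed = as.integer(seed)),
            class = "snj_config")
}

# concrete parameter values for a dataset of n taxa
resolve_config <- function(config, n) {
  stopifnot(inherits(config, "snj_config"))
  basic <- config$mode == "basic"
  k0 <- config$k0
  if (identical(k0, "auto"))
    k0 <- if (basic) 4L else ceiling(sqrt(n * log2(n)))
  k0 <- as.integer(min(max(4L, k0), n))
  s <- config$samples_per_subtree
  if (identical(s, "auto")) s <- if (basic) 1L else ceiling(log2(n))
  s <- as.integer(max(1L, s))
  o <- config$orienting_per_subtree
  if (is.null(o)) {
    o <- if (basic) 1L else min(3L, s)  # default clamps to the sampled count
  } else if (o < 1L || o > s) {
    stop("orienting_per_subtree must be in [1, samples_per_subtree]")
  }
  o <- as.integer(o)
  list(mode = config$mode, k0 = k0, samples_per_subtree = s,
       orienting_per_subtree = o, seed = config$seed)
}

#' Initial backbone tree from a random taxon subset
#'
#' Uniformly samples `k0` taxa, queries the dense distance block among them
#' (exactly `k0 (k0 - 1) / 2` distinct oracle queries), and builds the
#' backbone with canonical Neighbor Joining.  The remaining taxa are returned
#' in the shuffled order in which they will be inserted.
#'
#' @param oracle a `"distance_oracle"` over all taxa.
#' @param config an `"snj_config"`.
#' @param taxa taxa to use (defaults to all oracle taxa).
#' @return List with `backbone` (a `"topology"`), `backbone_taxa`,
#'   `remaining` (shuffled insertion order), and the resolved `params`.
#' @export
initial_backbone <- function(oracle, config = snj_config(),
                             taxa = oracle_taxa(oracle)) {
  n <- length(taxa)
  if (n < 4L) stop("need at least 4 taxa")
  prm <- resolve_config(config, n)
  ss <- substream_seeds(prm$seed, 3L)
  sel <- with_seed(ss[1L], sample_vec(seq_len(n), prm$k0))
  D0 <- oracle_block(oracle, taxa[sel])
  backbone <- neighbor_joining(D0)
  rest <- setdiff(seq_len(n), sel)
  ord <- with_seed(ss[2L], sample_vec(rest, length(rest)))
  list(backbone = backbone, backbone_taxa = taxa[sel],
       remaining = taxa[ord], params = prm, substreams = ss)
}

#' Averaged quartet distance matrix for a placement decision
#'
#' Builds the 4x4 matrix over {new taxon, A, B, C} where A, B, C are the
#' orienting-leaf sets of the three centroid components: the entry for the
#' new taxon against set i is the mean oracle distance to the members of set
#' i, and the entry between sets i and j is the mean over all cross pairs.
#' With singleton sets this is the plain 4-taxon distance matrix.
#'
#' @param new_taxon taxon name.
#' @param sets list of three non-empty character vectors of orienting leaves.
#' @param oracle a `"distance_oracle"`.
#' @return 4x4 symmetric matrix with dimnames `c(new_taxon, "A", "B", "C")`.
#' @export
build_quartet_matrix <- function(new_taxon, sets, oracle) {
  if (length(sets) != 3L || any(lengths(sets) == 0L))
    stop("three non-empty orienting sets required")
  M <- matrix(0, 4L, 4L, dimnames = rep(list(c(new_taxon, "A", "B", "C")), 2L))
  for (p in 1:3) {
    M[1L, p + 1L] <- M[p + 1L, 1L] <-
      mean(oracle_query(oracle, rep(new_taxon, length(sets[[p]])), sets[[p]]))
  }
  for (p in 1:2) for (q in (p + 1L):3L) {
    grid <- expand.grid(sets[[p]], sets[[q]], stringsAsFactors = FALSE)
    M[p + 1L, q + 1L] <- M[q + 1L, p + 1L] <-
      mean(oracle_query(oracle, grid[[1L]], grid[[2L]]))
  }
  M
}

#' Choose the centroid component a quartet points into
#'
#' Given the resolved quartet over {new taxon, A, B, C}, returns the index of
#' the component whose representative is paired with the new taxon.
#'
#' @param split a quartet as returned by [quartet_topology()].
#' @param new_taxon the new taxon's name as used in the quartet.
#' @param reps the three representative names, in component order.
#' @return The chosen component index (1, 2 or 3).
#' @export
select_subtree <- function(split, new_taxon, reps = c("A", "B", "C")) {
  inp1 <- new_taxon %in% split[[1L]]
  pair <- if (inp1) split[[1L]] else split[[2L]]
  if (!(new_taxon %in% pair)) stop("new taxon absent from the quartet")
  partner <- setdiff(pair, new_taxon)
  idx <- match(partner, reps)
  if (is.na(idx)) stop("quartet does not pair the new taxon with a representative")
  idx
}

#' Place one new taxon on a backbone tree
#'
#' Walks the centroid recursion: find the centroid of the current view,
#' decompose, draw candidate leaves per component (falling back to the
#' covering backbone component when a part has no leaves), keep the closest
#' as orienting leaves, resolve the quartet, and descend — until a single
#' edge remains.  The number of quartet rounds is logarithmic in the backbone
#' size.  If a quartet points past the view boundary (possible under noisy
#' distances), placement stops on the backbone edge leaving the centroid in
#' that direction.
#'
#' @param backbone a `"topology"` whose labels are known to the oracle.
#' @param new_taxon taxon to place (known to the oracle, not in the backbone).
#' @param oracle a `"distance_oracle"`.
#' @param config an `"snj_config"` (sampling counts are resolved against the
#'   oracle's taxon count).
#' @param seed integer seed for this placement's sampling.
#' @return List with `edge` (the chosen edge row of `backbone$edge`),
#'   `rounds` (quartet rounds used) and `fallback` (whether the boundary rule
#'   fired).
#' @export
place_leaf <- function(backbone, new_taxon, oracle, config = snj_config(),
                       seed = 1L) {
  taxa <- oracle_taxa(oracle)
  if (new_taxon %in% backbone$labels) stop("taxon already in the backbone")
  nt <- match(new_taxon, taxa)
  if (is.na(nt)) stop("new taxon unknown to the oracle")
  prm <- resolve_config(config, length(taxa))
  .snj_place_cpp(backbone$edge, max(topo_nodes(backbone)),
                 taxon_map(backbone, taxa), nt, oracle$ptr,
                 prm$samples_per_subtree, prm$orienting_per_subtree,
                 as.integer(seed))
}

#' Sparse Neighbor Joining inference
#'
#' Builds a topology on all oracle taxa: dense Neighbor Joining on a small
#' random initial subset, then one [place_leaf()] walk plus edge subdivision
#' per remaining taxon (in shuffled order).  Only the distances actually
#' demanded by the initial block and the quartet decisions are computed —
#' the oracle's distinct-query counter reports the realised cost.
#'
#' @param oracle a `"distance_oracle"` over the taxa to infer.
#' @param config an `"snj_config"`.
#' @return An object of class `"snj_run"`: `topology`, `params` (resolved),
#'   and `stats` (distinct queries, total pairs, query fraction, quartet
#'   rounds, boundary fallbacks).
#' @export
run_snj <- function(oracle, config = snj_config()) {
  taxa <- oracle_taxa(oracle)
  n <- length(taxa)
  init <- initial_backbone(oracle, config, taxa)
  prm <- init$params
  backbone <- init$backbone
  # backbone tips are 1..k0 in backbone_taxa order; map them to oracle indices
  tax0 <- taxon_map(backbone, taxa)
  ord <- match(init$remaining, taxa)
  if (length(ord)) {
    seeds <- with_seed(init$substreams[3L],
                       sample.int(.Machine$integer.max - 1L, length(ord)))
    res <- .snj_build_cpp(backbone$edge, max(topo_nodes(backbone)), tax0,
                          n, ord, oracle$ptr, prm$samples_per_subtree,
                          prm$orienting_per_subtree, seeds)
    tax <- res$taxon_of_node
    tips <- which(tax > 0L)
    topo <- topology(res$edge, tips, taxa[tax[tips]])
    rounds <- res$rounds
    fallbacks <- res$fallbacks
  } else {
    topo <- backbone
    rounds <- integer(0)
    fallbacks <- 0
  }
  st <- oracle_stats(oracle)
  structure(
    list(topology = topo, params = prm,
         insertion_order = init$remaining,
         stats = list(n = n,
                      distinct_queries = st$distinct_queries,
                      total_pairs = st$total_pairs,
                      query_fraction = st$query_fraction,
                      quartet_rounds = sum(rounds),
                      rounds_per_insertion = rounds,
                      fallbacks = fallbacks)),
    class = "snj_run")
}

#' @export
print.snj_run <- function(x, ...) {
  cat(sprintf("Sparse NJ run (%s mode): %d taxa\n", x$params$mode, x$stats$n))
  cat(sprintf("  k0 = %d, samples/subtree = %d, orienting/subtree = %d\n",
              x$params$k0, x$params$samples_per_subtree,
              x$params$orienting_per_subtree))
  cat(sprintf("  distinct distance queries: %s of %s (fraction %.4g)\n",
              format(x$stats$distinct_queries, big.mark = ","),
              format(x$stats$total_pairs, big.mark = ","),
              x$stats$query_fraction))
  invisible(x)
}
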