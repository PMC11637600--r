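#' Random tree topology by uniform pairwise merging
#'
#' Every taxon starts as its own component; two components are repeatedly
#' picked uniformly at random and merged under a new internal node until one
#' component remains, whose degree-2 top node is then suppressed.  The result
#' is a valid unrooted bifurcating topology.  Randomness comes from R's RNG.
#'
#' @param n number of leaves (>= 4).
#' @param labels leaf labels (default `t1..tn`).
#' @return A `"topology"` with tips at nodes `1..n`.
#' @export
random_topology <- function(n, labels = paste0("t", seq_len(n))) {
  if (n < 4L) stop("need at least 4 leaves")
  roots <- seq_len(n)
  nn <- n
  e1 <- integer(2L * n - 2L)
  e2 <- integer(2L * n - 2L)
  r <- 0L
  len <- n
  while (len > 1L) {
    pick <- sample.int(len, 2L)
    nn <- nn + 1L
    e1[r + 1L] <- nn; e2[r + 1L] <- roots[pick[1L]]
    e1[r + 2L] <- nn; e2[r + 2L] <- roots[pick[2L]]
    r <- r + 2L
    # swap-remove both picks, append the merged component
    keep <- pick[order(pick, decreasing = TRUE)]
    for (p in keep) {
      roots[p] <- roots[len]
      len <- len - 1L
    }
    len <- len + 1L
    roots[len] <- nn
  }
  # suppress the degree-2 top node (the last created, id 2n-1)
  top <- nn
  a <- e2[r - 1L]
  b <- e2[r]
  e1[r - 1L] <- a
  e2[r - 1L] <- b
  edge <- cbind(e1[seq_len(r - 1L)], e2[seq_len(r - 1L)])
  topology(edge, seq_len(n), labels)
}

#' Draw exponential branch lengths for a topology
#'
#' Branch lengths are i.i.d. exponential with mean `scale` (the default,
#' 1e-3 expected substitutions per site, gives the short-branch regime in
#' which sparse inference is stress-tested).
#'
#' @param t a `"topology"`.
#' @param scale mean branch length (exponential scale parameter).
#' @return A `"weighted_topology"`.
#' @export
draw_branch_lengths <- function(t, scale = 1e-3) {
  if (scale <= 0) stop("scale must be positive")
  weighted_topology(t, rexp(nrow(t$edge), rate = 1 / scale))
}

#' Evolve aligned sequences under the Jukes-Cantor model
#'
#' Roots the tree at an arbitrary internal node (the model is reversible, so
#' the choice does not affect the leaf distribution), draws the root sequence
#' uniformly over A/C/G/T, and substitutes each site independently along each
#' edge of length t with probability `(3/4)(1 - exp(-4t/3))`, choosing a
#' different base uniformly.  The exact per-edge transition probability is
#' used; no discretised steps.
#'
#' @param wt a `"weighted_topology"`.
#' @param m number of sites (>= 1).
#' @param root internal node to root the simulation at (default: the
#'   smallest internal node id); by reversibility the choice does not affect
#'   the leaf-sequence distribution.
#' @return A `"sequence_matrix"` of the leaf sequences.
#' @export
evolve_jc <- function(wt, m, root = NULL) {
  if (m < 1L) stop("need at least one site")
  t <- wt$topology
  nodes <- topo_nodes(t)
  nmax <- max(nodes)
  adj <- build_adjacency(t$edge, nmax)
  internal <- setdiff(nodes, t$tip)
  root <- root %||% min(internal)
  if (!(root %in% internal)) stop("root must be an internal node")
  seqs <- vector("list", nmax)
  seqs[[root]] <- sample.int(4L, m, replace = TRUE)
  tipcol <- integer(nmax)
  tipcol[t$tip] <- seq_along(t$tip)
  codes <- matrix(0L, m, length(t$tip))
  stack <- root
  parent <- integer(nmax)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nbrs <- adj$nbr[[v]]
    eids <- adj$eid[[v]]
    for (s in seq_along(nbrs)) {
      w <- nbrs[s]
      if (w == parent[v]) next
      parent[w] <- v
      p <- 0.75 * (1 - exp(-4 * wt$lengths[eids[s]] / 3))
      sq <- seqs[[v]]
      hit <- which(runif(m) < p)
      if (length(hit))
        sq[hit] <- (sq[hit] + sample.int(3L, length(hit), replace = TRUE) - 1L) %% 4L + 1L
      if (tipcol[w] > 0L) codes[, tipcol[w]] <- sq else seqs[[w]] <- sq
      stack <- c(stack, w)
    }
    seqs[v] <- list(NULL)  # free
  }
  new_sequence_matrix(t$labels, codes)
}

#' Exact path-length distance matrix of a weighted tree
#'
#' Sums of branch lengths along leaf-to-leaf paths; the resulting matrix is
#' additive (satisfies the four-point condition) and is the noiseless oracle
#' for exact-recovery experiments.
#'
#' @param wt a `"weighted_topology"`.
#' @return Symmetric numeric matrix, rows/columns in leaf-label order.
#' @export
path_distance_matrix <- function(wt) {
  phy <- as_phylo(wt)
  D <- ape::cophenetic.phylo(phy)
  D[wt$topology$labels, wt$topology$labels]
}

#' Simulate a full synthetic dataset
#'
#' Convenience wrapper for the standard synthetic recipe: random merge
#' topology, exponential branch lengths, Jukes-Cantor sequence evolution.
#'
#' @param n number of taxa.
#' @param m number of sites (0 to skip sequence simulation).
#' @param scale mean branch length.
#' @param seed RNG seed (the caller's RNG state is preserved).
#' @return List with `tree` (a `"weighted_topology"`) and `sequences` (a
#'   `"sequence_matrix"`, or `NULL` when `m = 0`).
#' @export
simulate_dataset <- function(n, m, scale = 1e-3, seed = 1L) {
  with_seed(seed, {
    wt <- draw_branch_lengths(random_topology(n), scale)
    sm <- if (m > 0L) evolve_jc(wt, m) else NULL
    list(tree = wt, sequences = sm)
  })
}
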