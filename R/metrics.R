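# ---- split (bipartition) machinery -----------------------------------------

# Normalise tree input for the metrics: a "topology" or an ape "phylo"
# (multifurcating reference trees are accepted) becomes a plain structure
# (edge matrix, tip node ids, labels).
as_edge_struct <- function(x) {
  if (inherits(x, "weighted_topology")) x <- x$topology
  if (inherits(x, "topology"))
    return(list(edge = x$edge, tip = x$tip, labels = x$labels))
  if (inherits(x, "phylo")) {
    if (ape::is.rooted(x)) x <- ape::unroot(x)
    k <- length(x$tip.label)
    return(list(edge = x$edge, tip = seq_len(k), labels = x$tip.label))
  }
  stop("expected a topology or phylo object")
}

# One bipartition row per edge: logical matrix over `universe` (sorted
# labels), each row the side NOT containing universe[1] (canonical
# orientation by construction: sides are accumulated away from that leaf).
edge_splits_core <- function(edge, tip, labels, universe) {
  k <- length(universe)
  nmax <- max(edge)
  adj <- build_adjacency(edge, nmax)
  uidx <- integer(nmax)
  uidx[tip] <- match(labels, universe)
  ref <- tip[match(universe[1L], labels)]
  parent <- integer(nmax)
  ord <- integer(0)
  stack <- ref
  parent[ref] <- -1L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ord <- c(ord, v)
    for (w in adj$nbr[[v]]) {
      if (w == parent[v]) next
      parent[w] <- v
      stack <- c(stack, w)
    }
  }
  S <- matrix(FALSE, nmax, k)
  for (v in rev(ord)) {
    if (uidx[v] > 0L) S[v, uidx[v]] <- TRUE
    if (parent[v] > 0L) S[parent[v], ] <- S[parent[v], ] | S[v, ]
  }
  out <- matrix(FALSE, nrow(edge), k)
  for (r in seq_len(nrow(edge))) {
    a <- edge[r, 1L]
    b <- edge[r, 2L]
    child <- if (parent[b] == a) b else a
    out[r, ] <- S[child, ]
  }
  out
}

split_sizes <- function(M) rowSums(M)

# canonical string keys for split rows
split_keys <- function(M) {
  pad <- (-ncol(M)) %% 8L
  apply(M, 1L, function(row)
    paste(packBits(c(row, logical(pad))), collapse = ""))
}

# shared universe of two trees, with validation
shared_universe <- function(a, b) {
  la <- sort(a$labels, method = "radix")
  lb <- sort(b$labels, method = "radix")
  if (!identical(la, lb)) stop("trees are over different leaf sets")
  if (length(la) < 4L) stop("tree comparison needs at least 4 leaves")
  la
}

# ---- Robinson-Foulds --------------------------------------------------------

#' Normalized Robinson-Foulds distance
#'
#' One minus the proportion of non-trivial bipartitions shared by the two
#' trees, normalised by the n-3 internal edges of a bifurcating tree on n
#' leaves (equivalently, the symmetric-difference count divided by 2(n-3)).
#' RF only asks whether a bipartition is identical in both trees, which makes
#' it saturate quickly; see [transfer_distance()] for a graded alternative.
#'
#' @param tree_a,tree_b trees on the same leaf set (`"topology"` or ape
#'   `"phylo"`).
#' @return Distance in `[0, 1]`.
#' @export
rf_distance <- function(tree_a, tree_b) {
  a <- as_edge_struct(tree_a)
  b <- as_edge_struct(tree_b)
  u <- shared_universe(a, b)
  n <- length(u)
  Ma <- edge_splits_core(a$edge, a$tip, a$labels, u)
  Mb <- edge_splits_core(b$edge, b$tip, b$labels, u)
  ka <- split_keys(Ma)[internal_rows(Ma)]
  kb <- split_keys(Mb)[internal_rows(Mb)]
  1 - sum(ka %in% kb) / (n - 3)
}

internal_rows <- function(M) {
  s <- rowSums(M)
  which(s >= 2 & s <= ncol(M) - 2)
}

# ---- transfer distance ------------------------------------------------------

# minimal per-reference-split transfer counts against all inferred edges
transfer_counts <- function(Rm, Em, n) {
  Rn <- Rm + 0
  En <- Em + 0
  mism <- Rn %*% t(1 - En) + (1 - Rn) %*% t(En)
  mism <- pmin(mism, n - mism)
  apply(mism, 1L, min)
}

#' Transfer index of one reference bipartition
#'
#' The minimal number of taxa that must change sides for some edge of the
#' inferred tree (trivial pendant edges included) to display the reference
#' bipartition, minimised over both orientations; normalised by the size of
#' the smaller side of the reference bipartition.
#'
#' @param side character vector: the taxa on one side of the reference
#'   bipartition (non-trivial over the inferred tree's leaf set).
#' @param tree the inferred tree (`"topology"` or `"phylo"`).
#' @return List with `count` and `normalized`.
#' @export
transfer_index <- function(side, tree) {
  b <- as_edge_struct(tree)
  u <- sort(b$labels, method = "radix")
  if (!all(side %in% u)) stop("split side contains unknown taxa")
  sz <- length(side)
  if (sz < 2L || sz > length(u) - 2L) stop("reference split is trivial")
  Rm <- matrix(u %in% side, 1L)
  Em <- edge_splits_core(b$edge, b$tip, b$labels, u)
  count <- transfer_counts(Rm, Em, length(u))
  list(count = as.integer(count),
       normalized = count / min(sz, length(u) - sz))
}

#' Transfer distance between two trees
#'
#' For each non-trivial reference edge, the [transfer_index()] against the
#' inferred tree, averaged over the n-3 reference edges.  Unlike
#' Robinson-Foulds, the transfer distance credits inferred edges that are
#' close to, but not identical with, a reference bipartition, so it degrades
#' gracefully and is the headline accuracy metric here.
#'
#' @param reference,inferred trees on the same leaf set (`"topology"` or
#'   `"phylo"`); the first argument is the reference whose edges are scored.
#' @return Mean normalised transfer index in `[0, 1]`.
#' @export
transfer_distance <- function(reference, inferred) {
  a <- as_edge_struct(reference)
  b <- as_edge_struct(inferred)
  u <- shared_universe(a, b)
  n <- length(u)
  Ma <- edge_splits_core(a$edge, a$tip, a$labels, u)
  ir <- internal_rows(Ma)
  if (length(ir) == 0L) return(0)
  Rm <- Ma[ir, , drop = FALSE]
  Em <- edge_splits_core(b$edge, b$tip, b$labels, u)
  counts <- transfer_counts(Rm, Em, n)
  sz <- rowSums(Rm)
  mean(counts / pmin(sz, n - sz))
}

# ---- quartet distance -------------------------------------------------------

# integer topological leaf-leaf distances
topo_leaf_distances <- function(es, universe) {
  nmax <- max(es$edge)
  adj <- build_adjacency(es$edge, nmax)
  k <- length(universe)
  tipnode <- es$tip[match(universe, es$labels)]
  D <- matrix(0L, k, k)
  for (i in seq_len(k)) {
    dist <- rep(NA_integer_, nmax)
    dist[tipnode[i]] <- 0L
    queue <- tipnode[i]
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      for (w in adj$nbr[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    D[i, ] <- dist[tipnode]
  }
  D
}

# induced quartet pairing for quadruple columns (4 x N matrix of leaf
# indices): 1 = (12|34), 2 = (13|24), 3 = (14|23), 0 = unresolved
quartet_pairings <- function(D, quad) {
  i <- quad[1L, ]; j <- quad[2L, ]; k <- quad[3L, ]; l <- quad[4L, ]
  s1 <- D[cbind(i, j)] + D[cbind(k, l)]
  s2 <- D[cbind(i, k)] + D[cbind(j, l)]
  s3 <- D[cbind(i, l)] + D[cbind(j, k)]
  p <- integer(length(i))
  p[s1 < s2 & s1 < s3] <- 1L
  p[s2 < s1 & s2 < s3] <- 2L
  p[s3 < s1 & s3 < s2] <- 3L
  p
}

#' Quartet distance between two trees
#'
#' The proportion of 4-leaf subsets whose induced unrooted quartet differs
#' between the trees.  Exact mode enumerates all `choose(n, 4)` quadruples
#' (allowed up to `exact_limit` leaves); sampled mode draws quadruples
#' uniformly and reports a binomial standard error in the `"stderr"`
#' attribute.  Quadruples left unresolved by a multifurcating reference
#' count as differing.
#'
#' @param tree_a,tree_b trees on the same leaf set.
#' @param mode `"auto"` (exact when feasible), `"exact"`, or `"sample"`.
#' @param n_samples quadruples drawn in sampled mode.
#' @param seed RNG seed for sampled mode.
#' @param exact_limit largest n for which exact enumeration is allowed.
#' @return Proportion in `[0, 1]`; sampled estimates carry `"stderr"` and
#'   `"n_samples"` attributes.
#' @export
quartet_distance <- function(tree_a, tree_b, mode = c("auto", "exact", "sample"),
                             n_samples = 500000L, seed = 1L,
                             exact_limit = 30L) {
  mode <- match.arg(mode)
  a <- as_edge_struct(tree_a)
  b <- as_edge_struct(tree_b)
  u <- shared_universe(a, b)
  n <- length(u)
  if (mode == "auto") mode <- if (n <= exact_limit) "exact" else "sample"
  if (mode == "exact" && n > exact_limit)
    stop(sprintf("exact quartet distance limited to %d leaves; use mode = \"sample\"",
                 exact_limit))
  Da <- topo_leaf_distances(a, u)
  Db <- topo_leaf_distances(b, u)
  if (mode == "exact") {
    quad <- utils::combn(n, 4L)
    pa <- quartet_pairings(Da, quad)
    pb <- quartet_pairings(Db, quad)
    return(mean(!(pa == pb & pa > 0L)))
  }
  quad <- with_seed(seed, draw_quadruples(n, n_samples))
  pa <- quartet_pairings(Da, quad)
  pb <- quartet_pairings(Db, quad)
  d <- mean(!(pa == pb & pa > 0L))
  attr(d, "stderr") <- sqrt(max(d * (1 - d), 1 / n_samples) / n_samples)
  attr(d, "n_samples") <- n_samples
  d
}

# uniform 4-subsets (as a 4 x N matrix), vectorised rejection sampling
draw_quadruples <- function(n, N) {
  out <- matrix(0L, 4L, 0L)
  while (ncol(out) < N) {
    need <- N - ncol(out)
    cand <- matrix(sample.int(n, 4L * ceiling(need * 1.15) + 8L,
                              replace = TRUE), nrow = 4L)
    ok <- cand[1L, ] != cand[2L, ] & cand[1L, ] != cand[3L, ] &
      cand[1L, ] != cand[4L, ] & cand[2L, ] != cand[3L, ] &
      cand[2L, ] != cand[4L, ] & cand[3L, ] != cand[4L, ]
    cand <- cand[, ok, drop = FALSE]
    if (ncol(cand) > need) cand <- cand[, seq_len(need), drop = FALSE]
    out <- cbind(out, cand)
  }
  out
}

# ---- edge displacement ------------------------------------------------------

#' Number of edges between two edges of a tree
#'
#' Counts the edges strictly between two edges on the path connecting them:
#' identical or adjacent edges are at displacement 0, edges separated by one
#' intervening edge at 1, and so on.  This is the per-insertion error
#' statistic: how far a chosen insertion edge lies from the edge the leaf
#' actually belongs to.
#'
#' @param tree a `"topology"`.
#' @param edge_a,edge_b edge row indices.
#' @return Non-negative integer.
#' @export
edge_displacement <- function(tree, edge_a, edge_b) {
  ne <- nrow(tree$edge)
  if (any(c(edge_a, edge_b) < 1L) || any(c(edge_a, edge_b) > ne))
    stop("edge index out of range")
  if (edge_a == edge_b) return(0L)
  nmax <- max(topo_nodes(tree))
  adj <- build_adjacency(tree$edge, nmax)
  ends_a <- tree$edge[edge_a, ]
  ends_b <- tree$edge[edge_b, ]
  best <- Inf
  for (s in ends_a) {
    dist <- rep(NA_integer_, nmax)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      for (w in adj$nbr[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    best <- min(best, dist[ends_b[1L]], dist[ends_b[2L]])
  }
  as.integer(best)
}

# ---- combined report --------------------------------------------------------

#' Compare an inferred tree against a reference
#'
#' Computes the Robinson-Foulds, transfer and quartet distances in one call.
#'
#' @param reference,inferred trees on the same leaf set.
#' @param metrics subset of `c("rf", "transfer", "quartet")`.
#' @param quartet_mode,quartet_samples,seed,exact_limit passed to
#'   [quartet_distance()].
#' @return An object of class `"tree_comparison"`: requested distances plus
#'   metadata (`n`, quartet mode/sample count/standard error, seed).
#' @export
compare_trees <- function(reference, inferred,
                          metrics = c("rf", "transfer", "quartet"),
                          quartet_mode = "auto", quartet_samples = 500000L,
                          seed = 1L, exact_limit = 30L) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  out <- list(n = length(as_edge_struct(reference)$labels))
  if ("rf" %in% metrics) out$rf <- rf_distance(reference, inferred)
  if ("transfer" %in% metrics)
    out$transfer <- transfer_distance(reference, inferred)
  if ("quartet" %in% metrics) {
    q <- quartet_distance(reference, inferred, mode = quartet_mode,
                          n_samples = quartet_samples, seed = seed,
                          exact_limit = exact_limit)
    out$quartet <- as.numeric(q)
    out$quartet_stderr <- attr(q, "stderr")
    out$quartet_samples <- attr(q, "n_samples")
    out$seed <- seed
  }
  structure(out, class = "tree_comparison")
}

#' @export
print.tree_comparison <- function(x, ...) {
  cat(sprintf("Tree comparison on %d leaves\n", x$n))
  if (!is.null(x$rf)) cat(sprintf("  RF (normalized):   %.4f\n", x$rf))
  if (!is.null(x$transfer)) cat(sprintf("  transfer distance: %.4f\n", x$transfer))
  if (!is.null(x$quartet)) {
    cat(sprintf("  quartet distance:  %.4f", x$quartet))
    if (!is.null(x$quartet_stderr))
      cat(sprintf(" (+/- %.4f, %d sampled quadruples)",
                  x$quartet_stderr, x$quartet_samples))
    cat("\n")
  }
  invisible(x)
}
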