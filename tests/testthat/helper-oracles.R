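# Independent brute-force oracles the implementation is validated against.
# Everything here is deliberately naive (exhaustive enumeration, BFS), and
# never calls the code path it checks.

# connected components of an edge subset after deleting one node;
# returns a list of integer vectors of edge row indices
components_without_node <- function(edge, edge_ids, drop_node) {
  edge <- edge[edge_ids, , drop = FALSE]
  remaining <- seq_len(nrow(edge))
  comps <- list()
  while (length(remaining)) {
    seed <- remaining[1L]
    comp <- seed
    frontier <- setdiff(as.vector(edge[seed, ]), drop_node)
    remaining <- remaining[-1L]
    while (length(frontier)) {
      v <- frontier[1L]
      frontier <- frontier[-1L]
      hit <- remaining[edge[remaining, 1L] == v | edge[remaining, 2L] == v]
      for (e in hit) {
        comp <- c(comp, e)
        frontier <- c(frontier, setdiff(as.vector(edge[e, ]), c(v, drop_node)))
      }
      remaining <- setdiff(remaining, hit)
    }
    comps[[length(comps) + 1L]] <- edge_ids[comp]
  }
  comps
}

# exhaustive centroid: minimise the max component leaf count over every
# qualifying node, ties by smallest node id
brute_centroid <- function(view) {
  t <- view$backbone
  sub <- t$edge[view$edges, , drop = FALSE]
  nodes <- sort(unique(as.vector(sub)))
  leaves <- intersect(nodes, t$tip)
  best <- NA_integer_
  best_mx <- Inf
  for (v in nodes) {
    if (sum(sub == v) < 2L) next
    comps <- components_without_node(t$edge, view$edges, v)
    mx <- if (length(comps)) {
      max(vapply(comps, function(ids) {
        cn <- setdiff(unique(as.vector(t$edge[ids, , drop = FALSE])), v)
        length(intersect(cn, leaves))
      }, numeric(1L)))
    } else 0
    if (mx < best_mx) {
      best <- v
      best_mx <- mx
    }
  }
  list(node = best, max_leaves = best_mx)
}

# all unrooted bifurcating topologies on the given labels (1, 3, 15, 105, ...)
enumerate_topologies <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 3L)
  star <- topology(cbind(4L, 1:3), 1:3, labels[1:3])
  trees <- list(star)
  if (n == 3L) return(trees)
  for (i in 4:n) {
    nxt <- list()
    for (t in trees) {
      for (e in seq_len(nrow(t$edge))) {
        nxt[[length(nxt) + 1L]] <- insert_leaf(t, e, labels[i])
      }
    }
    trees <- nxt
  }
  trees
}

# leaf labels on the side of edge `e` containing its second endpoint
edge_side <- function(t, e) {
  a <- t$edge[e, 1L]
  b <- t$edge[e, 2L]
  seen <- c(a, b)
  stack <- b
  edge <- t$edge
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    inc <- which(edge[, 1L] == v | edge[, 2L] == v)
    for (r in inc) {
      w <- setdiff(as.vector(edge[r, ]), v)
      if (r == e || w %in% seen) next
      seen <- c(seen, w)
      stack <- c(stack, w)
    }
  }
  side_nodes <- setdiff(seen, a)
  t$labels[t$tip %in% side_nodes]
}

# brute-force transfer distance: O(ref edges x est edges x n) double loop
brute_transfer <- function(ref, est) {
  u <- sort(ref$labels, method = "radix")
  n <- length(u)
  est_ind <- lapply(seq_len(nrow(est$edge)),
                    function(e) u %in% edge_side(est, e))
  total <- 0
  cnt <- 0L
  for (e in seq_len(nrow(ref$edge))) {
    side <- u %in% edge_side(ref, e)
    sz <- sum(side)
    if (sz < 2L || sz > n - 2L) next
    best <- Inf
    for (ei in est_ind) {
      mism <- sum(side != ei)
      best <- min(best, mism, n - mism)
    }
    total <- total + best / min(sz, n - sz)
    cnt <- cnt + 1L
  }
  total / cnt
}

# quartet "profile" of a tree: for every 4-leaf subset, the cherry pair of
# the pruned tree read directly off its edge structure (via ape's pruning,
# independent of the distance-sum route the package uses)
brute_quartet_profile <- function(t) {
  phy <- as_phylo(t)
  labs <- sort(t$labels, method = "radix")
  quads <- utils::combn(labs, 4L)
  apply(quads, 2L, function(q) {
    pr <- ape::keep.tip(phy, q)
    parent_of_tip <- pr$edge[match(1:4, pr$edge[, 2L]), 1L]
    cherry_parent <- names(which(table(parent_of_tip) == 2L))[1L]
    cherry <- sort(pr$tip.label[which(parent_of_tip == as.integer(cherry_parent))])
    if (!(q[1L] %in% cherry)) cherry <- sort(setdiff(q, cherry))
    paste(cherry, collapse = "|")
  })
}

# brute-force quartet distance from two profiles
brute_quartet <- function(a, b) {
  mean(brute_quartet_profile(a) != brute_quartet_profile(b))
}

# brute-force edge displacement: BFS over the edge-adjacency (line) graph
brute_edge_displacement <- function(t, ea, eb) {
  if (ea == eb) return(0L)
  ne <- nrow(t$edge)
  touches <- function(e1, e2) length(intersect(t$edge[e1, ], t$edge[e2, ])) > 0L
  dist <- rep(NA_integer_, ne)
  dist[ea] <- 0L
  queue <- ea
  while (length(queue)) {
    e <- queue[1L]
    queue <- queue[-1L]
    for (f in seq_len(ne)) {
      if (is.na(dist[f]) && touches(e, f)) {
        dist[f] <- dist[e] + 1L
        queue <- c(queue, f)
      }
    }
  }
  dist[eb] - 1L
}

# placement recomposed from the R-level module surface (basic variant):
# centroid -> decompose -> one sampled orienting leaf per part -> quartet
r_place_leaf <- function(backbone, new_taxon, oracle) {
  view <- subtree_view(backbone)
  repeat {
    if (length(view$edges) == 1L) return(view$edges)
    cen <- find_centroid(view)
    parts <- decompose(view, cen)
    reps <- lapply(parts, sample_leaves, count = 1L)
    M <- build_quartet_matrix(new_taxon, reps, oracle)
    q <- quartet_topology(M)
    idx <- select_subtree(q, new_taxon)
    if (length(parts[[idx]]$edges) == 0L)
      stop("quartet pointed outside the view")
    view <- parts[[idx]]
  }
}

# the backbone edge on which `label` truly attaches, by exhaustive insertion
brute_attachment_edge <- function(reference, backbone, label) {
  ind <- induced_topology(reference, c(backbone$labels, label))
  for (e in seq_len(nrow(backbone$edge))) {
    cand <- insert_leaf(backbone, e, label)
    if (rf_distance(cand, ind) == 0) return(e)
  }
  stop("no edge reproduces the reference attachment")
}

# random weighted tree shorthand
rand_wtree <- function(n, seed, scale = 1e-3) {
  simulate_dataset(n, 0L, scale = scale, seed = seed)$tree
}
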