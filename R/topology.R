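#' Unrooted bifurcating tree topology
#'
#' The basic tree object of the package: an unrooted, strictly bifurcating
#' topology over labelled leaves.  Internal nodes have degree exactly 3,
#' leaves degree 1; a tree on k leaves has 2k-2 nodes and 2k-3 edges.  Branch
#' lengths are deliberately not part of the object (the incremental inference
#' never stores them); see [weighted_topology()] for trees that carry them.
#'
#' @param edge integer matrix with one row per edge, two columns of node ids.
#' @param tip_nodes integer vector of leaf node ids.
#' @param labels character vector of taxon names, parallel to `tip_nodes`.
#' @param validate check structural invariants (degree, counts, connectivity).
#' @return An object of class `"topology"`.
#' @seealso [insert_leaf()], [read_newick()], [as_phylo()]
#' @export
topology <- function(edge, tip_nodes, labels, validate = TRUE) {
  storage.mode(edge) <- "integer"
  obj <- structure(
    list(edge = edge, tip = as.integer(tip_nodes), labels = as.character(labels)),
    class = "topology")
  if (validate) validate_topology(obj)
  obj
}

#' @export
print.topology <- function(x, ...) {
  k <- length(x$tip)
  cat(sprintf("Unrooted bifurcating topology: %d leaves, %d nodes, %d edges\n",
              k, length(topo_nodes(x)), nrow(x$edge)))
  cat("Leaves:", paste(head(sort(x$labels), 6L), collapse = ", "),
      if (k > 6L) "..." else "", "\n")
  invisible(x)
}

topo_nodes <- function(t) sort(unique(as.vector(t$edge)))

#' Number of leaves of a topology
#' @param t a `"topology"`.
#' @return Integer leaf count.
#' @export
n_leaves <- function(t) length(t$tip)

#' Leaf labels of a topology
#' @param t a `"topology"`.
#' @return Character vector of taxon names (in internal tip order).
#' @export
leaf_labels <- function(t) t$labels

#' Validate the structural invariants of a topology
#'
#' Checks that leaves have degree 1 and carry labels, internal nodes have
#' degree 3, the node/edge counts are 2k-2 and 2k-3, and the edge set is
#' connected and acyclic.
#'
#' @param t a `"topology"`.
#' @return `t`, invisibly; errors describe the violated invariant.
#' @export
validate_topology <- function(t) {
  edge <- t$edge
  if (anyDuplicated(t$labels)) stop("duplicated leaf labels")
  if (length(t$labels) != length(t$tip))
    stop("labels and tip_nodes lengths differ")
  nodes <- topo_nodes(t)
  k <- length(t$tip)
  if (k < 3L) stop("a topology needs at least 3 leaves")
  if (length(nodes) != 2L * k - 2L)
    stop(sprintf("expected %d nodes for %d leaves, found %d",
                 2L * k - 2L, k, length(nodes)))
  if (nrow(edge) != 2L * k - 3L)
    stop(sprintf("expected %d edges for %d leaves, found %d",
                 2L * k - 3L, k, nrow(edge)))
  deg <- tabulate(as.vector(edge), nbins = max(nodes))
  if (!all(deg[t$tip] == 1L)) stop("a labelled leaf does not have degree 1")
  internal <- setdiff(nodes, t$tip)
  if (!all(deg[internal] == 3L))
    stop("an internal node does not have degree 3")
  # connected + |E| = |V| - 1  =>  tree
  adj <- build_adjacency(edge, max(nodes))
  seen <- logical(max(nodes))
  stack <- nodes[1L]
  seen[stack] <- TRUE
  nseen <- 1L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in adj$nbr[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        nseen <- nseen + 1L
        stack <- c(stack, w)
      }
    }
  }
  if (nseen != length(nodes)) stop("edge set is disconnected")
  invisible(t)
}

# taxon index per node (0 = internal), taxa gives the index space
taxon_map <- function(t, taxa = t$labels) {
  tm <- integer(max(topo_nodes(t)))
  idx <- match(t$labels, taxa)
  if (anyNA(idx)) stop("topology labels missing from taxa")
  tm[t$tip] <- idx
  tm
}

#' Insert a new leaf on an edge of a topology
#'
#' Subdivides the chosen edge with a new internal node and attaches the new
#' leaf to it, turning a k-leaf topology into a (k+1)-leaf topology.  This is
#' the elementary update of the incremental inference: placing a taxon is
#' equivalent to choosing one of the 2k-3 backbone edges.
#'
#' @param t a `"topology"`.
#' @param edge edge row index (into `t$edge`) to subdivide.
#' @param label taxon name of the new leaf; must not already be present.
#' @return The updated `"topology"`.  The subdivided edge keeps its row index
#'   (now ending at the new internal node); two rows are appended.
#' @export
insert_leaf <- function(t, edge, label) {
  if (length(edge) != 1L || is.na(edge) || edge < 1L || edge > nrow(t$edge))
    stop("edge index out of range")
  if (label %in% t$labels) stop(sprintf("duplicate leaf label '%s'", label))
  u <- t$edge[edge, 1L]
  v <- t$edge[edge, 2L]
  w <- max(topo_nodes(t)) + 1L
  x <- w + 1L
  t$edge[edge, ] <- c(u, w)
  t$edge <- rbind(t$edge, c(w, v), c(w, x))
  t$tip <- c(t$tip, x)
  t$labels <- c(t$labels, label)
  validate_topology(t)
}

#' Remove a leaf from a topology
#'
#' Deletes the leaf and suppresses the degree-2 node left behind, so the
#' result is again a valid unrooted bifurcating topology.  Inverse of
#' [insert_leaf()] up to node numbering (split sets are preserved).
#'
#' @param t a `"topology"` with at least 4 leaves.
#' @param label taxon name of the leaf to remove.
#' @return The reduced `"topology"`.
#' @export
remove_leaf <- function(t, label) {
  i <- match(label, t$labels)
  if (is.na(i)) stop(sprintf("no leaf labelled '%s'", label))
  if (length(t$tip) < 4L) stop("cannot remove a leaf from a 3-leaf topology")
  x <- t$tip[i]
  rx <- which(t$edge[, 1L] == x | t$edge[, 2L] == x)
  w <- setdiff(as.vector(t$edge[rx, ]), x)
  rw <- setdiff(which(t$edge[, 1L] == w | t$edge[, 2L] == w), rx)
  ab <- setdiff(as.vector(t$edge[rw, ]), w)
  t$edge[rw[1L], ] <- ab
  t$edge <- t$edge[-c(rx, rw[2L]), , drop = FALSE]
  t$tip <- t$tip[-i]
  t$labels <- t$labels[-i]
  validate_topology(t)
}

#' Restrict a topology to a subset of its leaves
#'
#' @param t a `"topology"`.
#' @param labels leaf labels to keep (at least 3).
#' @return The induced `"topology"` on the kept leaves.
#' @export
induced_topology <- function(t, labels) {
  missing <- setdiff(labels, t$labels)
  if (length(missing)) stop("labels not in tree: ", paste(missing, collapse = ", "))
  if (length(labels) < 3L) stop("need at least 3 leaves")
  phy <- ape::keep.tip(as_phylo(t), labels)
  topology_from_phylo(phy)
}

#' Convert a topology to an ape "phylo" object
#'
#' @param t a `"topology"` or `"weighted_topology"`.
#' @param lengths optional numeric vector of branch lengths, one per row of
#'   `t$edge` (a `"weighted_topology"` supplies its own).
#' @return An unrooted `"phylo"` object (basal trifurcation).
#' @export
as_phylo <- function(t, lengths = NULL) {
  if (inherits(t, "weighted_topology")) {
    lengths <- lengths %||% t$lengths
    t <- t$topology
  }
  k <- length(t$tip)
  nodes <- topo_nodes(t)
  nmax <- max(nodes)
  adj <- build_adjacency(t$edge, nmax)
  # root at an internal node (neighbor of the first tip)
  root <- adj$nbr[[t$tip[1L]]][1L]
  map <- integer(nmax)
  map[t$tip] <- seq_len(k)
  # BFS assigning internal ids k+1.. in discovery order, collecting oriented edges
  nn <- length(nodes)
  parent_edge <- integer(0)
  edge_out <- matrix(0L, nrow(t$edge), 2L)
  elen <- if (!is.null(lengths)) numeric(nrow(t$edge)) else NULL
  map[root] <- k + 1L
  nexti <- k + 2L
  queue <- root
  visited <- logical(nmax)
  visited[root] <- TRUE
  r <- 0L
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    nbrs <- adj$nbr[[v]]
    eids <- adj$eid[[v]]
    for (s in seq_along(nbrs)) {
      w <- nbrs[s]
      if (visited[w]) next
      visited[w] <- TRUE
      if (map[w] == 0L) {
        map[w] <- nexti
        nexti <- nexti + 1L
      }
      r <- r + 1L
      edge_out[r, ] <- c(map[v], map[w])
      if (!is.null(elen)) elen[r] <- lengths[eids[s]]
      queue <- c(queue, w)
    }
  }
  phy <- list(edge = edge_out, tip.label = t$labels, Nnode = k - 2L)
  if (!is.null(elen)) phy$edge.length <- elen
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  phy
}

#' Convert an ape "phylo" object to a topology
#'
#' Branch lengths are dropped unless `lengths = TRUE`; a binary root is
#' collapsed so the result is unrooted.
#'
#' @param phy a `"phylo"` object; must be bifurcating (after unrooting).
#' @param lengths if `TRUE`, return a `"weighted_topology"` keeping
#'   `phy$edge.length`.
#' @return A `"topology"` (or `"weighted_topology"`).
#' @export
topology_from_phylo <- function(phy, lengths = FALSE) {
  if (!inherits(phy, "phylo")) stop("not a phylo object")
  if (ape::is.rooted(phy)) phy <- ape::unroot(phy)
  k <- length(phy$tip.label)
  t <- topology(phy$edge, seq_len(k), phy$tip.label)
  if (lengths) {
    if (is.null(phy$edge.length)) stop("phylo object has no branch lengths")
    weighted_topology(t, phy$edge.length)
  } else t
}

#' Read a tree from Newick
#'
#' @param file path to a Newick file (or use `text`).
#' @param text a Newick string.
#' @param lengths if `TRUE`, keep branch lengths and return a
#'   `"weighted_topology"`; by default lengths are ignored.
#' @return A `"topology"` or `"weighted_topology"`.
#' @export
read_newick <- function(file = NULL, text = NULL, lengths = FALSE) {
  phy <- if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text)
  if (is.null(phy)) stop("could not parse Newick input")
  topology_from_phylo(phy, lengths = lengths)
}

#' Write a tree as canonical Newick
#'
#' The output is canonicalised for reproducibility: the tree is written from
#' the internal node adjacent to the alphabetically first leaf, and children
#' are ordered by their smallest descendant label, so write -> read -> write
#' is byte-identical.
#'
#' @param t a `"topology"` or `"weighted_topology"`.
#' @param file optional output path; if `NULL` the Newick string is returned.
#' @param lengths optional per-edge lengths to write (a
#'   `"weighted_topology"` writes its own by default).
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(t, file = NULL, lengths = NULL) {
  if (inherits(t, "weighted_topology")) {
    lengths <- lengths %||% t$lengths
    t <- t$topology
  }
  bad <- grepl("[][();,:' \t]", t$labels) | t$labels == ""
  if (any(bad))
    stop("leaf labels contain Newick metacharacters: ",
         paste(t$labels[bad], collapse = ", "))
  nmax <- max(topo_nodes(t))
  adj <- build_adjacency(t$edge, nmax)
  lab <- character(nmax)
  lab[t$tip] <- t$labels
  ref_tip <- t$tip[which.min(rank_labels(t$labels))]
  root <- adj$nbr[[ref_tip]][1L]
  # iterative postorder: orient from root, then assemble strings bottom-up
  parent <- integer(nmax)
  pedge <- integer(nmax)
  order <- integer(0)
  stack <- root
  parent[root] <- -1L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order <- c(order, v)
    nbrs <- adj$nbr[[v]]
    eids <- adj$eid[[v]]
    for (s in seq_along(nbrs)) {
      w <- nbrs[s]
      if (w == parent[v]) next
      parent[w] <- v
      pedge[w] <- eids[s]
      stack <- c(stack, w)
    }
  }
  str <- character(nmax)
  minlab <- character(nmax)
  for (v in rev(order)) {
    if (lab[v] != "") {
      str[v] <- lab[v]
      minlab[v] <- lab[v]
    } else {
      ch <- setdiff(adj$nbr[[v]], parent[v])
      ch <- ch[order(rank_labels(minlab[ch]))]
      str[v] <- paste0("(", paste(str[ch], collapse = ","), ")")
      minlab[v] <- minlab[ch[1L]]
    }
    if (!is.null(lengths) && v != root)
      str[v] <- paste0(str[v], ":", format(lengths[pedge[v]], digits = 15L))
  }
  out <- paste0(str[root], ";")
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

# locale-independent label ordering
rank_labels <- function(x) {
  order(order(x, method = "radix"))
}

#' Weighted tree: a topology plus per-edge branch lengths
#'
#' @param topology a `"topology"`.
#' @param lengths positive numeric vector, one length per edge row, in
#'   expected substitutions per site.
#' @return An object of class `"weighted_topology"`.
#' @export
weighted_topology <- function(topology, lengths) {
  if (length(lengths) != nrow(topology$edge))
    stop("one branch length per edge required")
  if (any(lengths <= 0)) stop("branch lengths must be positive")
  structure(list(topology = topology, lengths = as.numeric(lengths)),
            class = "weighted_topology")
}

#' @export
print.weighted_topology <- function(x, ...) {
  print(x$topology)
  cat(sprintf("Branch lengths: min %.3g, median %.3g, max %.3g\n",
              min(x$lengths), stats::median(x$lengths), max(x$lengths)))
  invisible(x)
}

#' Shortest branch length of a weighted tree
#'
#' Half of this value is the convergence radius: if every pairwise distance
#' deviates from the true path length by less than half the shortest branch,
#' both Neighbor Joining and the sparse insertion procedure recover the true
#' topology exactly.
#'
#' @param wt a `"weighted_topology"`.
#' @return The minimum branch length.
#' @export
min_branch_length <- function(wt) min(wt$lengths)
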