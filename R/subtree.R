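#' Connected edge subset of a backbone topology
#'
#' A subtree view is the unit of the centroid recursion used for leaf
#' placement: a connected subset of backbone edges, together with the backbone
#' leaves that lie inside it.  Views produced by [decompose()] may have no
#' leaves of their own (all their boundary nodes are internal); such views
#' carry the leaf labels of the backbone component that covers them, from
#' which orienting leaves are then drawn.
#'
#' @param backbone a `"topology"`.
#' @param edges integer vector of edge row indices (default: all edges).
#' @param covering_leaves leaf labels of the covering backbone component, used
#'   only when the view itself contains no leaves (filled by [decompose()]).
#' @return An object of class `"subtree_view"`.
#' @export
subtree_view <- function(backbone, edges = seq_len(nrow(backbone$edge)),
                         covering_leaves = NULL) {
  edges <- as.integer(edges)
  if (length(edges) < 1L) stop("a view needs at least one edge")
  if (anyDuplicated(edges) || any(edges < 1L) || any(edges > nrow(backbone$edge)))
    stop("invalid edge indices")
  view_nodes <- unique(as.vector(backbone$edge[edges, , drop = FALSE]))
  leaf_idx <- which(backbone$tip %in% view_nodes)
  structure(
    list(backbone = backbone, edges = edges,
         leaf_nodes = backbone$tip[leaf_idx],
         leaf_labels = backbone$labels[leaf_idx],
         covering_leaves = covering_leaves),
    class = "subtree_view")
}

#' @export
print.subtree_view <- function(x, ...) {
  cat(sprintf("Subtree view: %d edges, %d leaves", length(x$edges),
              length(x$leaf_nodes)))
  if (length(x$leaf_nodes) == 0L && !is.null(x$covering_leaves))
    cat(sprintf(" (covered by a backbone component with %d leaves)",
                length(x$covering_leaves)))
  cat("\n")
  invisible(x)
}

#' Centroid of a subtree view
#'
#' Returns a node internal to the view whose removal splits the view into
#' connected components, each containing at most half of the view's leaves
#' (rounding up for odd counts); such a node always exists (Jordan's
#' classical centroid argument).  Among qualifying nodes the one minimising
#' the largest component leaf count is returned, remaining ties broken by
#' smallest node id, so the result is deterministic.
#'
#' @param view a `"subtree_view"` with at least 2 edges.
#' @return The centroid node id.
#' @export
find_centroid <- function(view) {
  if (length(view$edges) < 2L)
    stop("already terminal: a single-edge view has no centroid")
  t <- view$backbone
  res <- .snj_centroid_cpp(t$edge, max(topo_nodes(t)), taxon_map(t),
                           view$edges)
  if (!res$connected) stop("view edge set is disconnected")
  res$node
}

#' Decompose a subtree view at its centroid
#'
#' Removing the centroid (but no edges) splits the view into the (up to)
#' three parts hanging off the centroid's three backbone directions.  Parts
#' are returned in ascending order of the centroid's neighbouring node id.
#' When the centroid lies on the view's boundary, the missing directions come
#' back as empty views; these, and parts that contain edges but no leaves,
#' have `covering_leaves` filled with the leaf labels of the backbone
#' component on that side of the centroid, so orienting leaves can still be
#' sampled for them.
#'
#' @param view a `"subtree_view"`.
#' @param centroid a node internal to the view, as returned by
#'   [find_centroid()].
#' @return A list of three `"subtree_view"` objects (empty parts have a
#'   zero-length `edges` field).
#' @export
decompose <- function(view, centroid) {
  t <- view$backbone
  edge <- t$edge
  nmax <- max(topo_nodes(t))
  inview <- logical(nrow(edge))
  inview[view$edges] <- TRUE
  vnodes <- unique(as.vector(edge[view$edges, , drop = FALSE]))
  if (!(centroid %in% vnodes)) stop("centroid is not a node of the view")
  adj <- build_adjacency(edge, nmax)
  if (length(adj$nbr[[centroid]]) != 3L)
    stop("centroid must be an internal (degree-3) node")
  ord <- order(adj$nbr[[centroid]])
  parts <- vector("list", 3L)
  for (p in seq_len(3L)) {
    w <- adj$nbr[[centroid]][ord[p]]
    e <- adj$eid[[centroid]][ord[p]]
    if (!inview[e]) {
      # empty part: view does not extend in this backbone direction
      cover <- component_leaves(t, adj, avoid = centroid, from = w)
      parts[[p]] <- structure(
        list(backbone = t, edges = integer(0), leaf_nodes = integer(0),
             leaf_labels = character(0), covering_leaves = cover),
        class = "subtree_view")
      next
    }
    part_edges <- view_component(edge, adj, inview, avoid = centroid, from = w,
                                 first_edge = e)
    sv <- subtree_view(t, part_edges)
    if (length(sv$leaf_nodes) == 0L)
      sv$covering_leaves <- component_leaves(t, adj, avoid = centroid, from = w)
    parts[[p]] <- sv
  }
  parts
}

# edges of the in-view component reached from `from`, never crossing `avoid`
view_component <- function(edge, adj, inview, avoid, from, first_edge) {
  seen <- c(avoid, from)
  stack <- from
  out <- first_edge
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nbrs <- adj$nbr[[v]]
    eids <- adj$eid[[v]]
    for (s in seq_along(nbrs)) {
      if (!inview[eids[s]]) next
      w <- nbrs[s]
      if (w %in% seen) next
      seen <- c(seen, w)
      out <- c(out, eids[s])
      stack <- c(stack, w)
    }
  }
  sort(out)
}

# leaf labels of the full-backbone component reached from `from`, avoiding `avoid`
component_leaves <- function(t, adj, avoid, from) {
  seen <- c(avoid, from)
  stack <- from
  found <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in adj$nbr[[v]]) {
      if (w %in% seen) next
      seen <- c(seen, w)
      stack <- c(stack, w)
    }
  }
  tips <- t$tip[t$tip %in% seen & t$tip != avoid]
  t$labels[match(tips, t$tip)]
}

#' Sample candidate orienting leaves from a subtree view
#'
#' Draws a uniform sample without replacement from the view's leaves,
#' truncated to the number available.  A view with no leaves of its own falls
#' back to the leaves of its covering backbone component.  Randomness comes
#' from R's RNG, so results are reproducible under `set.seed()`.
#'
#' @param view a `"subtree_view"`.
#' @param count number of leaves requested (>= 1).
#' @return Character vector of sampled taxon names.
#' @export
sample_leaves <- function(view, count) {
  if (count < 1L) stop("count must be >= 1")
  pool <- view$leaf_labels
  if (length(pool) == 0L) pool <- view$covering_leaves
  if (length(pool) == 0L)
    stop("view has no leaves and no covering component")
  sample_vec(pool, min(count, length(pool)))
}
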