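#' Per-taxon average row sums of the Neighbor Joining criterion
#'
#' For an active distance matrix over n taxa, `u_i = sum_{j != i} D_ij /
#' (n - 2)`; the pair joined at each step is the one minimising
#' `D_ij - u_i - u_j`.
#'
#' @param D symmetric numeric matrix over at least 3 active taxa.
#' @return Numeric vector of u values.
#' @export
nj_u <- function(D) {
  n <- nrow(D)
  if (n < 3L) stop("u values are undefined for fewer than 3 active taxa")
  rowSums(D) / (n - 2)
}

#' One agglomeration step of Neighbor Joining
#'
#' Selects the pair minimising `D_ij - u_i - u_j` (ties broken by the
#' lexicographically smallest active-index pair) and reduces the matrix: the
#' joined pair is replaced, at the position of its smaller index, by a
#' cluster at distance `(D_ik + D_jk - D_ij) / 2` from every other taxon k;
#' the larger index's row and column are dropped.
#'
#' @param D symmetric numeric matrix over at least 3 active taxa.
#' @return List with `pair` (the two joined active indices, ascending) and
#'   `matrix` (the reduced matrix).
#' @export
nj_join_step <- function(D) {
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 active taxa to join")
  u <- nj_u(D)
  Q <- D - outer(u, u, `+`)
  diag(Q) <- Inf
  k <- which.min(Q)  # column-major first minimum = lexicographic (i, j) pair
  i <- (k - 1L) %% n + 1L
  j <- (k - 1L) %/% n + 1L
  a <- min(i, j)
  b <- max(i, j)
  dn <- (D[a, ] + D[b, ] - D[a, b]) / 2
  D[a, ] <- dn
  D[, a] <- dn
  D[a, a] <- 0
  if (!is.null(rownames(D))) {
    nm <- paste0("(", rownames(D)[a], ",", rownames(D)[b], ")")
    rownames(D)[a] <- colnames(D)[a] <- nm
  }
  list(pair = c(a, b), matrix = D[-b, -b, drop = FALSE])
}

#' Canonical Neighbor Joining
#'
#' The textbook O(n^3) agglomeration: repeatedly join the pair minimising
#' `D_ij - u_i - u_j` and reduce the matrix, until three clusters remain and
#' are attached to a final internal node.  Used as the dense baseline, to
#' build the sparse method's initial backbone, and (on 4 taxa) to resolve
#' quartets.  Only the topology is returned; branch lengths are not computed.
#'
#' @param x symmetric distance matrix with taxon dimnames, or a
#'   `"distance_oracle"` (the full block is then queried — this is the dense
#'   subroutine).
#' @param taxa optional taxon names overriding the dimnames.
#' @return A `"topology"` on the input taxa; tips are nodes `1..n` in input
#'   order.
#' @export
neighbor_joining <- function(x, taxa = NULL) {
  if (inherits(x, "distance_oracle")) x <- oracle_block(x)
  D <- as.matrix(x)
  taxa <- taxa %||% rownames(D)
  if (is.null(taxa)) stop("taxa names required")
  n <- length(taxa)
  if (n < 3L) stop("Neighbor Joining needs at least 3 taxa")
  act <- seq_len(n)          # tree node id of each active cluster
  nn <- n
  edge <- matrix(0L, 2L * n - 3L, 2L)
  r <- 0L
  rownames(D) <- colnames(D) <- taxa
  while (length(act) > 3L) {
    st <- nj_join_step(D)
    a <- st$pair[1L]
    b <- st$pair[2L]
    nn <- nn + 1L
    edge[r + 1L, ] <- c(nn, act[a])
    edge[r + 2L, ] <- c(nn, act[b])
    r <- r + 2L
    act[a] <- nn
    act <- act[-b]
    D <- st$matrix
  }
  nn <- nn + 1L
  for (s in seq_along(act)) {
    edge[r + s, ] <- c(nn, act[s])
  }
  topology(edge, seq_len(n), taxa)
}

#' Quartet topology by Neighbor Joining
#'
#' Resolves four taxa into two cherries using the first Neighbor Joining
#' join; on additive distances this is the four-point-condition minimiser.
#' Ties follow the [nj_join_step()] tie rule.
#'
#' @param D 4x4 symmetric distance matrix.
#' @param taxa the four taxon names (defaults to the dimnames).
#' @return A list of two character vectors, the two cherry pairs; each pair
#'   is sorted and the pair containing the first input taxon comes first.
#' @export
quartet_topology <- function(D, taxa = rownames(D)) {
  if (nrow(D) != 4L || ncol(D) != 4L) stop("quartet needs a 4x4 matrix")
  if (is.null(taxa) || length(taxa) != 4L) stop("four taxon names required")
  if (anyDuplicated(taxa)) stop("taxa must be distinct")
  st <- nj_join_step(unname(D))
  pair <- taxa[st$pair]
  rest <- setdiff(taxa, pair)
  first_has <- taxa[1L] %in% pair
  p1 <- sort(if (first_has) pair else rest)
  p2 <- sort(if (first_has) rest else pair)
  list(p1, p2)
}
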