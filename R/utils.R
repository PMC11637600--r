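# internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# derive k substream seeds from a master seed (kept below 2^31)
substream_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# sample without the length-1 surprise of sample()
sample_vec <- function(x, k) {
  x[sample.int(length(x), k)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# adjacency list (neighbors + incident edge row ids) from an edge matrix
build_adjacency <- function(edge, n_nodes = max(edge)) {
  ne <- nrow(edge)
  from <- c(edge[, 1L], edge[, 2L])
  to <- c(edge[, 2L], edge[, 1L])
  eid <- rep(seq_len(ne), 2L)
  ord <- order(from)
  f <- factor(from[ord], levels = seq_len(n_nodes))
  list(nbr = split(to[ord], f), eid = split(eid[ord], f))
}
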