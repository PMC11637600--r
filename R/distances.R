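#' Aligned DNA sequence matrix
#'
#' A thin container for an aligned DNA character matrix: taxon names plus an
#' integer-coded site-by-taxon matrix (A=1, C=2, G=3, T/U=4; anything else,
#' including gaps and ambiguity codes, is 0 and treated as non-comparable).
#'
#' @param x named character vector of aligned sequences (equal lengths), or a
#'   character matrix with one row per taxon.
#' @return An object of class `"sequence_matrix"` with fields `taxa`,
#'   `codes` (m-by-n integer matrix, one column per taxon) and `m`.
#' @export
sequence_matrix <- function(x) {
  if (is.matrix(x)) {
    taxa <- rownames(x)
    if (is.null(taxa)) stop("sequence matrix needs row names (taxa)")
    seqs <- apply(x, 1L, paste0, collapse = "")
  } else {
    taxa <- names(x)
    if (is.null(taxa)) stop("sequences must be named by taxon")
    seqs <- x
  }
  if (anyDuplicated(taxa)) stop("duplicated taxon names")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths differ (",
         paste(range(lens), collapse = "-"), ")")
  codes <- vapply(seqs, encode_dna, integer(lens[1L]))
  dimnames(codes) <- NULL
  new_sequence_matrix(taxa, codes)
}

new_sequence_matrix <- function(taxa, codes) {
  structure(list(taxa = taxa, codes = codes, m = nrow(codes)),
            class = "sequence_matrix")
}

#' @export
print.sequence_matrix <- function(x, ...) {
  cat(sprintf("Aligned DNA: %d taxa x %d sites\n", length(x$taxa), x$m))
  invisible(x)
}

encode_dna <- function(s) {
  v <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  code <- match(v, c("A", "C", "G", "T"))
  code[v == "U"] <- 4L
  code[is.na(code)] <- 0L
  code
}

decode_dna <- function(code) {
  paste0(c("-", "A", "C", "G", "T")[code + 1L], collapse = "")
}

#' Read an aligned FASTA file of DNA sequences
#'
#' @param file path to a FASTA file; all sequences must have equal length.
#' @return A `"sequence_matrix"`.
#' @export
read_fasta <- function(file) {
  dna <- ape::read.dna(file, format = "fasta", as.matrix = FALSE,
                       as.character = TRUE)
  if (is.matrix(dna)) {
    seqs <- apply(dna, 1L, paste0, collapse = "")
    names(seqs) <- rownames(dna)
  } else {
    seqs <- vapply(dna, paste0, character(1L), collapse = "")
  }
  sequence_matrix(seqs)
}

#' Write a sequence matrix as FASTA
#'
#' @param sm a `"sequence_matrix"`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(sm, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(sm$taxa)) {
    writeLines(paste0(">", sm$taxa[i]), con)
    writeLines(decode_dna(sm$codes[, i]), con)
  }
  invisible(file)
}

#' Count mismatching and comparable sites between two aligned sequences
#'
#' Only sites where both sequences have an unambiguous A/C/G/T are compared
#' (pairwise deletion); a mismatch is a comparable site with different bases.
#'
#' @param seq_i,seq_j aligned sequences: single strings, character vectors of
#'   residues, or integer code vectors as stored in a `"sequence_matrix"`.
#' @return Named integer vector `c(mismatch = , comparable = )`.
#' @export
hamming_mismatch <- function(seq_i, seq_j) {
  ci <- as_codes(seq_i)
  cj <- as_codes(seq_j)
  if (length(ci) != length(cj))
    stop(sprintf("sequence lengths differ (%d vs %d)", length(ci), length(cj)))
  comparable <- ci > 0L & cj > 0L
  c(mismatch = sum(comparable & ci != cj), comparable = sum(comparable))
}

as_codes <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  if (is.character(x) && length(x) == 1L) return(encode_dna(x))
  if (is.character(x)) return(encode_dna(paste0(x, collapse = "")))
  stop("cannot interpret sequence input")
}

#' Jukes-Cantor distance from mismatch counts
#'
#' The closed-form maximum-likelihood branch length estimate under the
#' Jukes-Cantor model, `-(3/4) * log(1 - (4/3) * p)` with `p` the mismatch
#' proportion over comparable sites, in expected substitutions per site.
#' When `p >= 3/4` the estimator diverges (saturation) and the configured cap
#' is returned instead; the `"saturated"` attribute flags such entries.
#'
#' @param mismatch,comparable counts as returned by [hamming_mismatch()]
#'   (vectorised).
#' @param cap distance assigned to saturated pairs (default 10 expected
#'   substitutions/site).
#' @return Numeric vector of distances with a logical `"saturated"` attribute.
#' @export
jc_distance <- function(mismatch, comparable, cap = 10) {
  if (any(comparable == 0L)) stop("no comparable sites")
  if (any(mismatch > comparable) || any(mismatch < 0L))
    stop("mismatch count outside [0, comparable]")
  p <- mismatch / comparable
  arg <- 1 - (4 / 3) * p
  sat <- arg <= 0
  d <- ifelse(sat, cap, -0.75 * log(pmax(arg, 1e-300)))
  sat <- sat | d > cap
  d <- pmin(d, cap)
  attr(d, "saturated") <- sat
  d
}

#' Read a PHYLIP distance matrix
#'
#' Accepts both the square and the lower-triangular dialect, auto-detected
#' from the row shapes.  Asymmetries up to `tol` are symmetrised by
#' averaging; larger asymmetries (or a malformed layout) are an error.
#'
#' @param file path to a PHYLIP distance-matrix file.
#' @param tol symmetry tolerance for square matrices.
#' @return Symmetric numeric matrix with taxon dimnames.
#' @export
read_phylip_distances <- function(file, tol = 1e-9) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 2L) stop("first line must give the number of taxa")
  if (length(lines) != n + 1L)
    stop(sprintf("expected %d matrix rows, found %d", n, length(lines) - 1L))
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "[ \t]+")[[1L]])
  taxa <- vapply(rows, `[`, character(1L), 1L)
  if (anyDuplicated(taxa)) stop("duplicated taxon names in matrix")
  vals <- lapply(rows, function(r) suppressWarnings(as.numeric(r[-1L])))
  if (any(vapply(vals, anyNA, logical(1L)))) stop("non-numeric distance entry")
  counts <- lengths(vals)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  if (all(counts == n)) {
    for (i in seq_len(n)) D[i, ] <- vals[[i]]
    asym <- max(abs(D - t(D)))
    if (asym > tol)
      stop(sprintf("matrix asymmetry %.3g exceeds tolerance %.3g", asym, tol))
    if (asym > 0) {
      warning("symmetrising slightly asymmetric input by averaging")
      D <- (D + t(D)) / 2
    }
  } else if (all(counts == seq_len(n) - 1L)) {
    for (i in seq_len(n)[-1L]) {
      D[i, seq_len(i - 1L)] <- vals[[i]]
      D[seq_len(i - 1L), i] <- vals[[i]]
    }
  } else {
    stop("rows match neither the square nor the lower-triangular layout")
  }
  if (any(D < 0)) stop("negative distances")
  D
}

#' Write a PHYLIP (square) distance matrix
#'
#' @param D symmetric numeric matrix with taxon dimnames.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_phylip_distances <- function(D, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(D)), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste(c(rownames(D)[i], sprintf("%.12g", D[i, ])),
                     collapse = " "), con)
  invisible(file)
}

# ---- distance oracles -------------------------------------------------------

#' Memoizing pairwise-distance oracles
#'
#' A distance oracle answers pairwise-distance queries from a backing source,
#' caches every computed entry, and counts how many *distinct* unordered
#' pairs were ever computed.  The distinct-query counter is the cost model of
#' the sparse inference: it measures how much of the n(n-1)/2 matrix a method
#' actually touched.
#'
#' Three backings are available: a precomputed symmetric matrix, an aligned
#' sequence matrix (Jukes-Cantor or raw mismatch-proportion distances,
#' computed on demand), and a weighted tree (exact path-length sums, the
#' noiseless oracle used to exercise the exact-recovery guarantee).  All
#' backings optionally add a bounded uniform perturbation, drawn
#' deterministically per unordered pair, used to probe the convergence radius
#' (recovery remains exact while the perturbation stays below half the
#' shortest branch length).
#'
#' @param D symmetric numeric matrix with taxon dimnames.
#' @param x a `"sequence_matrix"` (or input accepted by [sequence_matrix()]).
#' @param wt a `"weighted_topology"`.
#' @param distance `"jc"` for Jukes-Cantor or `"hamming"` for the raw
#'   mismatch proportion.
#' @param cap saturation cap for Jukes-Cantor distances.
#' @param noise half-width of the uniform per-pair perturbation (0 = none).
#' @param noise_seed integer seed for the perturbation stream.
#' @return An object of class `"distance_oracle"`.
#' @name distance_oracles
NULL

new_oracle <- function(ptr, taxa, backing, distance = NA_character_) {
  structure(list(ptr = ptr, taxa = taxa, backing = backing,
                 distance = distance),
            class = "distance_oracle")
}

#' @rdname distance_oracles
#' @export
matrix_oracle <- function(D, noise = 0, noise_seed = 1L) {
  taxa <- rownames(D)
  if (is.null(taxa)) stop("distance matrix needs taxon dimnames")
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix is not symmetric")
  new_oracle(.oracle_matrix_cpp(D, taxa, noise, as.integer(noise_seed)),
             taxa, "matrix")
}

#' @rdname distance_oracles
#' @export
sequence_oracle <- function(x, distance = c("jc", "hamming"), cap = 10,
                            noise = 0, noise_seed = 1L) {
  distance <- match.arg(distance)
  sm <- if (inherits(x, "sequence_matrix")) x else sequence_matrix(x)
  new_oracle(.oracle_sequences_cpp(sm$codes, sm$taxa, distance == "jc", cap,
                                   noise, as.integer(noise_seed)),
             sm$taxa, "sequences", distance)
}

#' @rdname distance_oracles
#' @export
tree_oracle <- function(wt, noise = 0, noise_seed = 1L) {
  if (!inherits(wt, "weighted_topology")) stop("need a weighted_topology")
  t <- wt$topology
  new_oracle(.oracle_tree_cpp(t$edge, wt$lengths, t$tip, t$labels,
                              max(topo_nodes(t)), noise,
                              as.integer(noise_seed)),
             t$labels, "tree")
}

#' @export
print.distance_oracle <- function(x, ...) {
  st <- oracle_stats(x)
  cat(sprintf("Distance oracle (%s backing): %d taxa, %d distinct pairs queried\n",
              x$backing, length(x$taxa), st$distinct_queries))
  invisible(x)
}

#' Query a distance oracle
#'
#' Vectorised over pairs.  Cached entries are returned without recomputation;
#' each previously unseen unordered pair increments the distinct-query
#' counter by one.  Self-distances are 0 and are not counted.
#'
#' @param oracle a `"distance_oracle"`.
#' @param i,j taxon names or indices (recycled to a common length).
#' @return Numeric vector of distances.
#' @export
oracle_query <- function(oracle, i, j) {
  ii <- resolve_taxa(oracle, i)
  jj <- resolve_taxa(oracle, j)
  .oracle_query_cpp(oracle$ptr, ii, jj)
}

resolve_taxa <- function(oracle, x) {
  if (is.character(x)) {
    idx <- match(x, oracle$taxa)
    if (anyNA(idx)) stop("unknown taxon: ", paste(x[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(x)
}

#' Dense distance block among a subset of taxa
#'
#' Queries every unordered pair within the subset through the memoizing path
#' (so the distinct-query counter reflects exactly the pairs computed) and
#' returns the symmetric block.  This is the dense subroutine that the sparse
#' method confines to the small initial backbone and to quartets.
#'
#' @param oracle a `"distance_oracle"`.
#' @param taxa taxon names or indices.
#' @return Symmetric numeric matrix with the taxa as dimnames.
#' @export
oracle_block <- function(oracle, taxa = oracle$taxa) {
  idx <- resolve_taxa(oracle, taxa)
  B <- .oracle_block_cpp(oracle$ptr, idx)
  dimnames(B) <- list(oracle$taxa[idx], oracle$taxa[idx])
  B
}

#' Oracle query statistics
#'
#' @param oracle a `"distance_oracle"`.
#' @return List with `n_taxa`, `distinct_queries` (number of distinct
#'   unordered pairs ever computed), `total_pairs` (n(n-1)/2),
#'   `query_fraction`, and `saturated` (count of capped Jukes-Cantor
#'   entries).
#' @export
oracle_stats <- function(oracle) {
  st <- .oracle_stats_cpp(oracle$ptr)
  n <- st$n_taxa
  total <- n * (n - 1) / 2
  list(n_taxa = n, distinct_queries = st$distinct_queries,
       total_pairs = total,
       query_fraction = st$distinct_queries / total,
       saturated = st$saturated)
}

#' Taxa known to an oracle
#' @param oracle a `"distance_oracle"`.
#' @return Character vector of taxon names.
#' @export
oracle_taxa <- function(oracle) oracle$taxa
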