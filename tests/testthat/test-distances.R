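test_that("hamming_mismatch counts comparable and differing sites", {
  expect_equal(hamming_mismatch("ACGT", "ACGT"),
               c(mismatch = 0L, comparable = 4L))
  expect_equal(hamming_mismatch("ACGT", "ACGA"),
               c(mismatch = 1L, comparable = 4L))
  # gaps and ambiguity codes drop the site from both counts
  expect_equal(hamming_mismatch("AC-T", "ACGT"),
               c(mismatch = 0L, comparable = 3L))
  expect_equal(hamming_mismatch("ANGT", "ACGA"),
               c(mismatch = 1L, comparable = 3L))
  # U is treated as T
  expect_equal(hamming_mismatch("ACGU", "ACGT"),
               c(mismatch = 0L, comparable = 4L))
  expect_error(hamming_mismatch("ACG", "ACGT"), "lengths differ")
})

test_that("jc_distance matches the closed form, caps at saturation, and is monotone", {
  expect_equal(as.numeric(jc_distance(0L, 1000L)), 0)
  d <- jc_distance(1000L, 10000L)
  expect_equal(as.numeric(d), -0.75 * log(1 - (4 / 3) * 0.1), tolerance = 1e-14)
  expect_false(attr(d, "saturated"))
  # p = 3/4 exactly: the estimator diverges -> cap + flag
  sat <- jc_distance(7500L, 10000L, cap = 10)
  expect_equal(as.numeric(sat), 10)
  expect_true(attr(sat, "saturated"))
  # strictly increasing in p below saturation
  p <- seq(0, 0.74, by = 0.01)
  dd <- as.numeric(jc_distance(as.integer(p * 10000), 10000L))
  expect_true(all(diff(dd) > 0))
  expect_error(jc_distance(1L, 0L), "comparable")
})

test_that("the oracle memoizes: repeated queries count once", {
  D <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3L,
              dimnames = rep(list(c("a", "b", "c")), 2L))
  o <- matrix_oracle(D)
  for (i in 1:10) expect_equal(oracle_query(o, "a", "b"), 1)
  expect_equal(oracle_stats(o)$distinct_queries, 1)
  expect_equal(oracle_query(o, "b", "a"), 1)  # unordered pair
  expect_equal(oracle_stats(o)$distinct_queries, 1)
  expect_equal(oracle_query(o, "a", "a"), 0)  # self distance not counted
  expect_equal(oracle_stats(o)$distinct_queries, 1)
  expect_error(oracle_query(o, "a", "zzz"), "unknown taxon")
})

test_that("tree-backed oracle returns exact path sums", {
  # quartet ((a,b),(c,d)) with unit branch lengths: cherry mates at 2, others at 3
  q <- topology(cbind(c(5L, 5L, 5L, 6L, 6L), c(1L, 2L, 6L, 3L, 4L)),
                1:4, c("a", "b", "c", "d"))
  wt <- weighted_topology(q, rep(1, 5))
  o <- tree_oracle(wt)
  expect_equal(oracle_query(o, "a", "b"), 2)
  expect_equal(oracle_query(o, "a", "c"), 3)
  expect_equal(oracle_query(o, "c", "d"), 2)
  # agrees with the independent path-sum matrix on larger trees
  wt2 <- rand_wtree(25, seed = 3)
  o2 <- tree_oracle(wt2)
  D <- path_distance_matrix(wt2)
  labs <- wt2$topology$labels
  for (rep in 1:50) {
    ij <- sample(labs, 2L)
    expect_equal(oracle_query(o2, ij[1L], ij[2L]), D[ij[1L], ij[2L]],
                 tolerance = 1e-12)
  }
})

test_that("tree oracle distances satisfy the four-point condition", {
  wt <- rand_wtree(12, seed = 9)
  o <- tree_oracle(wt)
  labs <- wt$topology$labels
  quads <- utils::combn(labs, 4L)
  for (c_i in seq_len(ncol(quads))) {
    q <- quads[, c_i]
    s <- c(oracle_query(o, q[1L], q[2L]) + oracle_query(o, q[3L], q[4L]),
           oracle_query(o, q[1L], q[3L]) + oracle_query(o, q[2L], q[4L]),
           oracle_query(o, q[1L], q[4L]) + oracle_query(o, q[2L], q[3L]))
    s <- sort(s, decreasing = TRUE)
    expect_lt(abs(s[1L] - s[2L]), 1e-12 * max(s[1L], 1e-12))
  }
})

test_that("sequence-backed oracle equals jc_distance of hamming_mismatch", {
  set.seed(5)
  dat <- simulate_dataset(8, 400, scale = 0.02, seed = 5)
  o <- sequence_oracle(dat$sequences)
  sm <- dat$sequences
  for (rep in 1:20) {
    ij <- sample(length(sm$taxa), 2L)
    hm <- hamming_mismatch(sm$codes[, ij[1L]], sm$codes[, ij[2L]])
    expect_equal(oracle_query(o, ij[1L], ij[2L]),
                 as.numeric(jc_distance(hm[["mismatch"]], hm[["comparable"]])),
                 tolerance = 1e-12)
  }
  # hamming backing returns the raw proportion
  oh <- sequence_oracle(dat$sequences, distance = "hamming")
  ij <- c(1L, 2L)
  hm <- hamming_mismatch(sm$codes[, 1L], sm$codes[, 2L])
  expect_equal(oracle_query(oh, 1L, 2L),
               hm[["mismatch"]] / hm[["comparable"]], tolerance = 1e-12)
})

test_that("per-pair perturbation is bounded and reproducible", {
  wt <- rand_wtree(15, seed = 13, scale = 0.1)
  clean <- tree_oracle(wt)
  noisy1 <- tree_oracle(wt, noise = 0.02, noise_seed = 7)
  noisy2 <- tree_oracle(wt, noise = 0.02, noise_seed = 7)
  labs <- wt$topology$labels
  for (rep in 1:40) {
    ij <- sample(labs, 2L)
    d0 <- oracle_query(clean, ij[1L], ij[2L])
    d1 <- oracle_query(noisy1, ij[1L], ij[2L])
    expect_lt(abs(d1 - d0), 0.02)
    expect_equal(oracle_query(noisy2, ij[1L], ij[2L]), d1)
  }
})

test_that("PHYLIP distance matrices read in both dialects", {
  D <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3L,
              dimnames = rep(list(c("a", "b", "c")), 2L))
  fsq <- tempfile()
  write_phylip_distances(D, fsq)
  expect_equal(read_phylip_distances(fsq), D)
  flt <- tempfile()
  writeLines(c("3", "a", "b 1", "c 2 3"), flt)
  expect_equal(read_phylip_distances(flt), D)
  # asymmetry beyond tolerance is an error
  fbad <- tempfile()
  writeLines(c("3", "a 0 1 2", "b 1.5 0 3", "c 2 3 0"), fbad)
  expect_error(read_phylip_distances(fbad), "asymmetry")
  # small asymmetry symmetrises with a warning
  fsym <- tempfile()
  writeLines(c("3", "a 0 1 2", "b 1.0000000001 0 3", "c 2 3 0"), fsym)
  expect_warning(Ds <- read_phylip_distances(fsym, tol = 1e-6), "symmetris")
  expect_equal(Ds, D, tolerance = 1e-9)
  unlink(c(fsq, flt, fbad, fsym))
})

test_that("FASTA round-trips and malformed alignments are rejected", {
  dat <- simulate_dataset(6, 50, seed = 8)
  f <- tempfile(fileext = ".fasta")
  write_fasta(dat$sequences, f)
  back <- read_fasta(f)
  expect_identical(back$taxa, dat$sequences$taxa)
  expect_identical(back$codes, dat$sequences$codes)
  unlink(f)
  expect_error(sequence_matrix(c(a = "ACGT", b = "ACG")), "ragged")
  expect_error(sequence_matrix(setNames(c("ACGT", "ACGT"), c("a", "a"))),
               "duplicated")
})
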