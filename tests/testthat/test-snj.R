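test_that("initial backbone: size, query cost and determinism", {
  wt <- rand_wtree(30, seed = 1)
  o <- tree_oracle(wt)
  cfg <- snj_config(mode = "enhanced", k0 = 10L, seed = 5)
  init <- initial_backbone(o, cfg)
  expect_equal(n_leaves(init$backbone), 10L)
  expect_equal(oracle_stats(o)$distinct_queries, choose(10, 2))
  expect_setequal(c(init$backbone_taxa, init$remaining),
                  wt$topology$labels)
  # same seed, fresh oracle: identical backbone and insertion order
  init2 <- initial_backbone(tree_oracle(wt), cfg)
  expect_identical(init2$backbone_taxa, init$backbone_taxa)
  expect_identical(init2$remaining, init$remaining)
  expect_identical(write_newick(init2$backbone), write_newick(init$backbone))
  # n = 4: the backbone is the NJ quartet, nothing remains
  wt4 <- rand_wtree(4, seed = 2)
  o4 <- tree_oracle(wt4)
  init4 <- initial_backbone(o4, snj_config(mode = "basic", seed = 1))
  expect_length(init4$remaining, 0L)
  expect_equal(rf_distance(init4$backbone, wt4$topology), 0)
})

test_that("build_quartet_matrix averages over orienting sets", {
  wt <- rand_wtree(12, seed = 3, scale = 0.5)
  o <- tree_oracle(wt)
  labs <- wt$topology$labels
  # singleton sets give the plain 4-taxon matrix
  M1 <- build_quartet_matrix(labs[1L], list(labs[2L], labs[3L], labs[4L]), o)
  expect_equal(M1[1L, 2L], oracle_query(o, labs[1L], labs[2L]))
  expect_equal(M1[3L, 4L], oracle_query(o, labs[3L], labs[4L]))
  expect_equal(M1, t(M1))
  expect_equal(diag(M1), setNames(rep(0, 4), rownames(M1)))
  # sets of size 3: every entry is the literal mean over member pairs
  sets <- list(labs[2:4], labs[5:7], labs[8:10])
  M3 <- build_quartet_matrix(labs[1L], sets, o)
  for (p in 1:3) {
    expect_equal(M3[1L, p + 1L],
                 mean(sapply(sets[[p]], function(x)
                   oracle_query(o, labs[1L], x))))
  }
  for (p in 1:2) for (q in (p + 1L):3L) {
    vals <- outer(sets[[p]], sets[[q]],
                  Vectorize(function(x, y) oracle_query(o, x, y)))
    expect_equal(M3[p + 1L, q + 1L], mean(vals))
  }
  expect_error(build_quartet_matrix(labs[1L],
                                    list(labs[2L], character(0), labs[3L]), o),
               "non-empty")
})

test_that("select_subtree follows the new taxon's cherry partner", {
  expect_equal(select_subtree(list(c("A", "x"), c("B", "C")), "x"), 1L)
  expect_equal(select_subtree(list(c("B", "x"), c("A", "C")), "x"), 2L)
  expect_equal(select_subtree(list(c("A", "B"), c("C", "x")), "x"), 3L)
  expect_error(select_subtree(list(c("A", "B"), c("C", "D")), "x"), "absent")
})

test_that("noiseless placement finds the true attachment edge", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(5:60, 1L)
    wt <- rand_wtree(n, seed = 400 + rep)
    truth <- wt$topology
    lab <- sample(truth$labels, 1L)
    backbone <- remove_leaf(truth, lab)
    o <- tree_oracle(wt)
    for (mode in c("basic", "enhanced")) {
      pl <- place_leaf(backbone, lab, o, snj_config(mode = mode, seed = rep),
                       seed = rep)
      expect_equal(rf_distance(insert_leaf(backbone, pl$edge, lab), truth), 0)
      expect_false(pl$fallback)
    }
  }
})

test_that("a 3-leaf backbone is resolved in a single quartet round", {
  wt <- rand_wtree(4, seed = 11)
  truth <- wt$topology
  lab <- truth$labels[1L]
  backbone <- remove_leaf(truth, lab)
  pl <- place_leaf(backbone, lab, tree_oracle(wt), snj_config(mode = "basic"),
                   seed = 1)
  expect_equal(pl$rounds, 1L)
  expect_equal(rf_distance(insert_leaf(backbone, pl$edge, lab), truth), 0)
})

test_that("the C++ walk and the R module-surface walk place identically (noiseless)", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(6:40, 1L)
    wt <- rand_wtree(n, seed = 500 + rep)
    truth <- wt$topology
    lab <- sample(truth$labels, 1L)
    backbone <- remove_leaf(truth, lab)
    o <- tree_oracle(wt)
    cpp_edge <- place_leaf(backbone, lab, o,
                           snj_config(mode = "basic"), seed = rep)$edge
    r_edge <- r_place_leaf(backbone, lab, o)
    expect_equal(r_edge, cpp_edge)
  }
})

test_that("quartet rounds stay within the logarithmic bound", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(10:200, 1L)
    wt <- rand_wtree(n, seed = 600 + rep)
    fit <- run_snj(tree_oracle(wt), snj_config(seed = rep))
    k <- seq(fit$params$k0, n - 1L)
    bound <- ceiling(log2(2 * k - 3)) + 2
    expect_true(all(fit$stats$rounds_per_insertion <= bound))
  }
})

test_that("noiseless full runs recover the true topology in both modes", {
  set.seed(19)
  for (n in c(10L, 50L, 200L)) {
    wt <- rand_wtree(n, seed = n)
    for (mode in c("basic", "enhanced")) {
      fit <- run_snj(tree_oracle(wt), snj_config(mode = mode, seed = n + 1L))
      expect_equal(rf_distance(wt$topology, fit$topology), 0)
    }
  }
  # n = 4 reduces to plain Neighbor Joining
  wt4 <- rand_wtree(4, seed = 23)
  o <- tree_oracle(wt4)
  fit4 <- run_snj(o, snj_config(seed = 1))
  expect_equal(rf_distance(fit4$topology, neighbor_joining(oracle_block(o))), 0)
})

test_that("runs are reproducible from the master seed", {
  wt <- rand_wtree(40, seed = 29)
  f1 <- run_snj(tree_oracle(wt), snj_config(seed = 77))
  f2 <- run_snj(tree_oracle(wt), snj_config(seed = 77))
  expect_identical(write_newick(f1$topology), write_newick(f2$topology))
  expect_identical(f1$stats$distinct_queries, f2$stats$distinct_queries)
  f3 <- run_snj(tree_oracle(wt), snj_config(seed = 78))
  expect_false(identical(f1$insertion_order, f3$insertion_order))
})

test_that("basic-mode query count respects the per-insertion budget", {
  n <- 1000L
  wt <- rand_wtree(n, seed = 31)
  o <- tree_oracle(wt)
  fit <- run_snj(o, snj_config(mode = "basic", seed = 1))
  # each quartet round needs at most 6 fresh pairs; plus the 6 initial ones
  budget <- 6 + 6 * sum(ceiling(log2(2 * seq(4L, n - 1L) - 3)) + 2)
  expect_lte(oracle_stats(o)$distinct_queries, budget)
  # and the realised count is O(n log n)-sized: a small multiple of n log2 n
  expect_lte(oracle_stats(o)$distinct_queries, 6 * n * log2(n))
})

test_that("query fraction decreases with the number of taxa", {
  fracs <- sapply(c(250L, 500L, 1000L, 2000L), function(n) {
    wt <- rand_wtree(n, seed = n + 3L)
    run_snj(tree_oracle(wt), snj_config(seed = 1))$stats$query_fraction
  })
  expect_true(all(diff(fracs) < 0))
})

test_that("recovery survives oracle noise below half the shortest branch", {
  set.seed(37)
  for (rep in 1:20) {
    n <- sample(5:50, 1L)
    wt <- rand_wtree(n, seed = 700 + rep)
    o <- tree_oracle(wt, noise = 0.45 * min_branch_length(wt),
                     noise_seed = rep)
    fit <- run_snj(o, snj_config(seed = rep))
    expect_equal(rf_distance(wt$topology, fit$topology), 0)
  }
})

test_that("config validation catches inconsistent settings", {
  wt <- rand_wtree(10, seed = 1)
  o <- tree_oracle(wt)
  expect_error(run_snj(o, snj_config(samples_per_subtree = 2L,
                                     orienting_per_subtree = 5L)),
               "orienting_per_subtree")
})
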