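test_that("identical trees are at distance zero under every metric", {
  t <- with_seed_test(1, random_topology(12))
  expect_equal(rf_distance(t, t), 0)
  expect_equal(transfer_distance(t, t), 0)
  expect_equal(quartet_distance(t, t, mode = "exact"), 0)
})

test_that("trees one NNI apart on 5 leaves differ in exactly one of two splits", {
  base <- enumerate_topologies(paste0("t", 1:5))[[1L]]
  # find an enumerated tree sharing exactly one internal split
  others <- enumerate_topologies(paste0("t", 1:5))
  rfs <- vapply(others, function(o) rf_distance(base, o), numeric(1L))
  expect_true(any(abs(rfs - 0.5) < 1e-12))
  one_nni <- others[[which(abs(rfs - 0.5) < 1e-12)[1L]]]
  expect_equal(rf_distance(base, one_nni), 1 / 2)
  q <- quartet_distance(base, one_nni, mode = "exact")
  expect_equal(q, brute_quartet(base, one_nni))
  expect_gt(q, 0)
})

test_that("RF agrees with phangorn on random tree pairs", {
  set.seed(3)
  for (rep in 1:25) {
    n <- sample(5:40, 1L)
    a <- random_topology(n)
    b <- random_topology(n)
    mine <- rf_distance(a, b)
    theirs <- phangorn::RF.dist(as_phylo(a), as_phylo(b)) / (2 * (n - 3))
    expect_equal(mine, theirs, tolerance = 1e-12)
  }
  expect_error(rf_distance(random_topology(6),
                           random_topology(6, labels = paste0("x", 1:6))),
               "different leaf sets")
})

test_that("transfer index: recovered splits cost zero, all values bounded by one", {
  set.seed(4)
  t <- random_topology(10)
  u <- sort(t$labels, method = "radix")
  for (e in seq_len(nrow(t$edge))) {
    side <- edge_side(t, e)
    if (length(side) < 2L || length(side) > 8L) next
    ti <- transfer_index(side, t)
    expect_equal(ti$count, 0L)
    expect_equal(ti$normalized, 0)
  }
  # against a different tree: exhaustive-scan oracle, and the <= 1 bound
  b <- random_topology(10)
  for (e in seq_len(nrow(t$edge))) {
    side <- edge_side(t, e)
    if (length(side) < 2L || length(side) > 8L) next
    ti <- transfer_index(side, b)
    brute <- min(sapply(seq_len(nrow(b$edge)), function(f) {
      mism <- sum(xor(u %in% side, u %in% edge_side(b, f)))
      min(mism, 10 - mism)
    }))
    expect_equal(ti$count, brute)
    expect_lte(ti$normalized, 1)
  }
})

test_that("transfer distance equals the brute-force double loop", {
  # exhaustive over all 5-leaf topology pairs
  all5 <- enumerate_topologies(paste0("t", 1:5))
  for (a in all5) for (b in all5) {
    expect_equal(transfer_distance(a, b), brute_transfer(a, b),
                 tolerance = 1e-12)
  }
  # random pairs on 6-8 leaves
  set.seed(5)
  for (rep in 1:40) {
    n <- sample(6:8, 1L)
    a <- random_topology(n)
    b <- random_topology(n)
    expect_equal(transfer_distance(a, b), brute_transfer(a, b),
                 tolerance = 1e-12)
  }
})

test_that("transfer and RF vanish together", {
  set.seed(6)
  for (rep in 1:30) {
    n <- sample(5:15, 1L)
    a <- random_topology(n)
    b <- if (rep %% 2L) random_topology(n) else a
    rf <- rf_distance(a, b)
    td <- transfer_distance(a, b)
    expect_equal(rf == 0, td == 0)
  }
})

test_that("RF saturates where transfer degrades gracefully", {
  # a 20-leaf caterpillar with one end leaf re-attached at the far end:
  # almost every split changes slightly, so RF jumps while transfer stays low
  n <- 20L
  t <- enumerate_topologies(paste0("t", 1:4))[[1L]]
  for (i in 5:n) {
    e <- which(t$edge[, 1L] == t$tip[length(t$tip)] |
                 t$edge[, 2L] == t$tip[length(t$tip)])
    t <- insert_leaf(t, e, paste0("t", i))
  }
  moved <- remove_leaf(t, "t20")
  e1 <- which(moved$edge[, 1L] == moved$tip[1L] |
                moved$edge[, 2L] == moved$tip[1L])
  moved <- insert_leaf(moved, e1, "t20")
  rf <- rf_distance(t, moved)
  td <- transfer_distance(t, moved)
  expect_gt(rf, 0.8)
  expect_lt(td, 0.2)
  expect_equal(td, brute_transfer(t, moved), tolerance = 1e-12)
})

test_that("exact quartet distance matches the prune-and-compare oracle", {
  set.seed(7)
  for (rep in 1:12) {
    n <- sample(5:8, 1L)
    a <- random_topology(n)
    b <- random_topology(n)
    expect_equal(quartet_distance(a, b, mode = "exact"), brute_quartet(a, b),
                 tolerance = 1e-12)
  }
})

test_that("sampled quartet distance tracks the exact value within its standard error", {
  set.seed(8)
  bad <- 0L
  trials <- 40L
  for (rep in seq_len(trials)) {
    a <- random_topology(20)
    b <- random_topology(20)
    ex <- quartet_distance(a, b, mode = "exact")
    sm <- quartet_distance(a, b, mode = "sample", n_samples = 4000L,
                           seed = rep)
    if (abs(as.numeric(sm) - ex) > 3 * attr(sm, "stderr")) bad <- bad + 1L
  }
  expect_lte(bad, 2L)
  expect_error(quartet_distance(random_topology(40), random_topology(40),
                                mode = "exact"), "sample")
})

test_that("multifurcating reference trees are accepted, unresolved quartets differ", {
  star <- ape::read.tree(text = "(a,b,c,d,e);")
  t <- read_newick(text = "((a,b),c,(d,e));")
  expect_equal(quartet_distance(star, t, mode = "exact"), 1)
  expect_equal(rf_distance(star, t), 1)  # no shared non-trivial splits
})

test_that("edge displacement matches BFS over edge adjacency", {
  # 8-leaf caterpillar, all edge pairs
  t <- enumerate_topologies(paste0("t", 1:4))[[1L]]
  for (i in 5:8) {
    e <- which(t$edge[, 1L] == t$tip[length(t$tip)] |
                 t$edge[, 2L] == t$tip[length(t$tip)])
    t <- insert_leaf(t, e, paste0("t", i))
  }
  ne <- nrow(t$edge)
  for (a in seq_len(ne)) for (b in seq_len(ne)) {
    expect_equal(edge_displacement(t, a, b), brute_edge_displacement(t, a, b))
  }
  expect_equal(edge_displacement(t, 3L, 3L), 0L)
  expect_error(edge_displacement(t, 1L, 99L), "out of range")
})

test_that("compare_trees assembles a coherent report", {
  set.seed(9)
  a <- random_topology(15)
  b <- random_topology(15)
  rep <- compare_trees(a, b, quartet_mode = "exact")
  expect_s3_class(rep, "tree_comparison")
  expect_equal(rep$rf, rf_distance(a, b))
  expect_equal(rep$transfer, transfer_distance(a, b))
  expect_equal(rep$quartet, as.numeric(quartet_distance(a, b, mode = "exact")))
  expect_true(all(unlist(rep[c("rf", "transfer", "quartet")]) >= 0))
  expect_true(all(unlist(rep[c("rf", "transfer", "quartet")]) <= 1))
})
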