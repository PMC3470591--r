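test_that("node SS sums squared similarities over unordered pairs", {
  S <- rbind(c(2, 2, 1), c(2, 2, 0), c(1, 0, 2))
  expect_equal(node_ss(1L, S), 0)             # singleton
  expect_equal(node_ss(c(1L, 2L), S), 4)      # one pair, 2^2
  expect_equal(node_ss(1:3, S), 4 + 1 + 0)    # three pairs enumerated by hand
})

test_that("node quality equals the hand-computed cross-leaf sum", {
  # {a,b,c,d} split into leaves {a,b} and {c,d}, all similarities 2:
  # 4 cross pairs x 2^2 = 16
  S <- matrix(2, 4, 4)
  node <- list(members = 1:4, children = list(
    list(members = 1:2, children = NULL),
    list(members = 3:4, children = NULL)))
  expect_equal(node_quality(node, S), 16)
  # leaves with zero cross-similarity give zero quality
  S0 <- block_similarity(c(2, 2))
  expect_equal(node_quality(node, S0), 0)
  expect_error(node_quality(list(members = 1:2, children = NULL), S), "internal")
})

test_that("SS-difference quality identically equals cross-leaf summation", {
  set.seed(21)
  g <- geno_matrix(matrix(sample(0:2, 18 * 120, replace = TRUE), 18, 120))
  S <- asd_similarity(g)
  tree <- build_tree(S, min_node_size = 3)
  check_node <- function(node) {
    if (is.null(node$children)) return(invisible())
    expect_equal(node_quality(node, S), quality_cross_leaf(node, unclass(S)),
                 tolerance = 1e-10)
    for (ch in node$children) check_node(ch)
  }
  check_node(tree$root)
  expect_gt(tree$n_leaves, 1L)
})

test_that("build_tree recovers exact block structure", {
  # two blocks: root with two leaf children matching the blocks
  S2 <- block_similarity(c(4, 5))
  t2 <- build_tree(S2, min_node_size = 4)
  expect_equal(t2$n_leaves, 2L)
  kids <- lapply(t2$root$children, `[[`, "members")
  expect_setequal(vapply(kids, length, integer(1L)), c(4L, 5L))
  expect_true(setequal(kids[[1]], 1:4) || setequal(kids[[1]], 5:9))
  # three mutually dissimilar blocks of 3: the three leaves are the blocks
  # whatever split order the recursion takes
  S3 <- block_similarity(c(3, 3, 3))
  t3 <- build_tree(S3, min_node_size = 3)
  leaves <- ships:::.collect_leaves(t3$root)
  expect_equal(length(leaves), 3L)
  expect_setequal(lapply(leaves, sort), list(1:3, 4:6, 7:9))
})

test_that("homogeneous data yield a single-leaf tree and a k=1 sequence", {
  S <- matrix(2, 6, 6)  # identical samples
  rownames(S) <- colnames(S) <- paste0("s", 1:6)
  tree <- build_tree(S)
  expect_equal(tree$n_leaves, 1L)
  parts <- prune_sequence(tree, S)
  expect_equal(length(parts), 1L)
  expect_equal(unname(parts[[1]]), rep(1L, 6))
})

test_that("pruning yields nested partitions from K_built down to 1", {
  set.seed(33)
  g <- block_genotypes(c(8, 8, 8), 250, seed = 33)
  S <- asd_similarity(g)
  tree <- build_tree(S, min_node_size = 3)
  parts <- prune_sequence(tree, S)
  ks <- attr(parts, "ks")
  expect_equal(ks[1], tree$n_leaves)
  expect_equal(ks[length(ks)], 1L)
  expect_true(all(diff(ks) < 0))  # strictly decreasing k
  # coarsening: every cluster of a later partition is a union of clusters of
  # the earlier one, i.e. cluster co-membership never breaks
  for (i in seq_len(length(parts) - 1L)) {
    fine <- parts[[i]]; coarse <- parts[[i + 1L]]
    crossed <- table(fine, coarse)
    expect_true(all(rowSums(crossed > 0) == 1L))
  }
  # labels contiguous 1..k and every sample assigned
  for (pp in parts) {
    expect_setequal(unique(pp), seq_len(max(pp)))
    expect_equal(length(pp), 24L)
  }
})

test_that("a single-split tree prunes to exactly two partitions", {
  S <- block_similarity(c(3, 4))
  tree <- build_tree(S, min_node_size = 3)
  parts <- prune_sequence(tree, S)
  expect_equal(attr(parts, "ks"), c(2L, 1L))
  expect_equal(unname(parts[[1]]), rep(1:2, c(3, 4)))
  expect_equal(unname(parts[[2]]), rep(1L, 7))
})

test_that("dispersion is monotone along the prune sequence", {
  set.seed(44)
  g <- block_genotypes(c(6, 6, 6, 6), 300, seed = 44)
  S <- asd_similarity(g)
  tree <- build_tree(S, min_node_size = 3)
  parts <- prune_sequence(tree, S)
  D <- dissimilarity_from_similarity(S)
  W <- vapply(parts, within_dispersion, numeric(1), D = D)
  expect_true(all(diff(W) >= -1e-10))  # merging clusters never decreases W
})
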