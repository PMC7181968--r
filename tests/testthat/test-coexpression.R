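test_that("correlation matrix is symmetric with unit diagonal and flags constants", {
  set.seed(4)
  expr <- matrix(rnorm(5 * 40), 5, 40,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:40)))
  expr["g2", ] <- expr["g1", ]          # duplicate row
  expr["g3", ] <- -expr["g1", ]         # negated row
  expr["g5", ] <- 7                     # constant
  cm <- correlation_matrix(expr)
  expect_equal(cm["g1", "g2"], 1)
  expect_equal(cm["g1", "g3"], -1)
  expect_true(isTRUE(all.equal(cm[!is.na(cm)], t(cm)[!is.na(t(cm))])))
  expect_equal(attr(cm, "constant_genes"), "g5")
  expect_true(all(is.na(cm["g5", ])))
  expect_error(correlation_matrix(expr[, 1:2]), "at least 3 samples")
})

test_that("independent genes stay far below the network cutoff", {
  set.seed(11)
  expr <- matrix(rnorm(30 * 1000), 30, 1000,
                 dimnames = list(paste0("g", 1:30), paste0("s", 1:1000)))
  cm <- correlation_matrix(expr)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.2)
})

test_that("network keeps exactly the pairs at or above the cutoff", {
  e <- generate_expression(40, 100, block_sizes = 6, block_rho = 0.999, seed = 23)
  cm <- correlation_matrix(log2(e$expression))
  net <- build_network(cm, cutoff = 0.99)
  blk <- e$truth$coexpr_blocks[[1]]
  expect_setequal(igraph::V(net)$name, blk)
  expect_equal(igraph::ecount(net), choose(6, 2))
  # impossible cutoff: empty network
  empty <- build_network(cm, cutoff = 1.01)
  expect_equal(igraph::vcount(empty), 0)
  # edges invariant under sample permutation
  perm <- sample(ncol(e$expression))
  cm2 <- correlation_matrix(log2(e$expression[, perm]))
  net2 <- build_network(cm2, cutoff = 0.99)
  el <- function(g) {
    m <- igraph::as_edgelist(g)
    sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
  }
  expect_equal(el(net2), el(net))
})

test_that("quantile mode keeps the top fraction of pairs", {
  set.seed(2)
  expr <- matrix(rnorm(20 * 50), 20, 50,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:50)))
  cm <- correlation_matrix(expr)
  net <- build_network(cm, cutoff = 0.1, mode = "quantile")
  expect_equal(igraph::ecount(net), floor(choose(20, 2) * 0.1), tolerance = 1)
})

test_that("walktrap splits disjoint cliques and keeps one clique together", {
  cliq <- function(genes) {
    cm <- matrix(1, length(genes), length(genes), dimnames = list(genes, genes))
    cm
  }
  cm <- matrix(0, 10, 10, dimnames = list(paste0("g", 1:10), paste0("g", 1:10)))
  cm[1:5, 1:5] <- 1; cm[6:10, 6:10] <- 1; diag(cm) <- 1
  net <- build_network(cm, cutoff = 0.99)
  part <- walktrap_communities(net)
  expect_equal(length(unique(part)), 2)
  expect_equal(length(unique(part[paste0("g", 1:5)])), 1)
  # single clique: one community
  net1 <- build_network(cliq(paste0("h", 1:6)), cutoff = 0.99)
  expect_equal(length(unique(walktrap_communities(net1))), 1)
  # a partition is a partition
  expect_setequal(names(part), igraph::V(net)$name)
})

test_that("planted blocks are recovered as communities and filtered sensibly", {
  e <- generate_expression(80, 120, block_sizes = c(6, 8), block_rho = 0.995,
                           seed = 37)
  cm <- correlation_matrix(log2(e$expression))
  net <- build_network(cm, cutoff = 0.99)
  part <- walktrap_communities(net)
  blocks <- e$truth$coexpr_blocks
  truth_labels <- rep(seq_along(blocks), lengths(blocks))
  names(truth_labels) <- unlist(blocks)
  common <- intersect(names(part), names(truth_labels))
  expect_setequal(common, names(truth_labels))
  expect_equal(ari(part[common], truth_labels[common]), 1.0)

  kept <- filter_clusters(part, cm, min_size = 5, min_corr = 0.5)
  expect_length(kept, 2)
  expect_setequal(unlist(lapply(kept, `[[`, "genes")), names(truth_labels))
  for (cl in kept) expect_gt(cl$mean_correlation, 0.9)
})

test_that("cluster filtering is monotone in its thresholds", {
  e <- generate_expression(80, 120, block_sizes = c(5, 7, 9), block_rho = 0.995,
                           seed = 41)
  cm <- correlation_matrix(log2(e$expression))
  net <- build_network(cm, cutoff = 0.99)
  part <- walktrap_communities(net)
  ids <- function(cls) vapply(cls, `[[`, numeric(1), "id")
  base <- ids(filter_clusters(part, cm, min_size = 5, min_corr = 0.5))
  expect_true(all(ids(filter_clusters(part, cm, min_size = 7, min_corr = 0.5)) %in% base))
  expect_true(all(ids(filter_clusters(part, cm, min_size = 5, min_corr = 0.95)) %in% base))
  # explicit drops: a 4-gene cluster and a low-correlation cluster
  cm2 <- diag(10); dimnames(cm2) <- list(paste0("x", 1:10), paste0("x", 1:10))
  cm2[1:4, 1:4] <- 0.99; diag(cm2) <- 1
  part2 <- setNames(c(rep(1, 4), rep(2, 6)), paste0("x", 1:10))
  expect_length(filter_clusters(part2, cm2, min_size = 5, min_corr = 0.5), 0)
})

test_that("top_neighbors returns ranked partners above the floor", {
  e <- generate_expression(40, 150, block_sizes = 9, block_rho = 0.995, seed = 3)
  cm <- correlation_matrix(log2(e$expression))
  blk <- e$truth$coexpr_blocks[[1]]
  nb <- top_neighbors(cm, blk[1], n = 8, min_corr = 0.9)
  expect_setequal(names(nb), setdiff(blk, blk[1]))
  expect_true(all(diff(nb) <= 0))
  # tiny block: fewer neighbors than n
  e2 <- generate_expression(30, 150, block_sizes = 3, block_rho = 0.999, seed = 5)
  cm2 <- correlation_matrix(log2(e2$expression))
  blk2 <- e2$truth$coexpr_blocks[[1]]
  expect_length(top_neighbors(cm2, blk2[1], n = 8, min_corr = 0.9), 2)
  # isolated gene: empty result; absent gene: error
  expect_length(top_neighbors(cm2, rownames(cm2)[30], n = 8, min_corr = 0.9), 0)
  expect_error(top_neighbors(cm2, "nope"), "not in correlation matrix")
})
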