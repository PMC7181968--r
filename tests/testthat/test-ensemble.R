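test_that("hamming distance equals the reaction-set symmetric difference", {
  toy <- generate_toy_gem(2, seed = 6)$model
  expect_equal(hamming_distance(toy, toy), 0)
  m2 <- remove_reactions(toy, model_reactions(toy)[2])
  expect_equal(hamming_distance(toy, m2), 1)
  # spec-style example: {a,b,c} vs {b,d} -> 3, via presence vectors
  set.seed(15)
  base <- generate_toy_gem(3, seed = 15)$model
  ens <- generate_ensemble(base, n_models = 12, n_variable_reactions = 18,
                           separation = 9, noise = 0.3, seed = 15)
  presence <- vapply(ens$models, function(m)
    ens$truth$variable_reactions %in% model_reactions(m), logical(18))
  D <- distance_matrix(ens$models)
  for (i in 1:11) for (j in (i + 1):12) {
    expect_equal(D[i, j], sum(presence[, i] != presence[, j]))
  }
})

test_that("distance matrix is a metric: symmetry, zero diagonal, triangle", {
  base <- generate_toy_gem(2, seed = 8)$model
  ens <- generate_ensemble(base, n_models = 10, n_variable_reactions = 12,
                           separation = 6, noise = 0.2, seed = 8)
  D <- distance_matrix(ens$models)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  n <- nrow(D)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(D[i, j], D[i, k] + D[k, j])
  # duplicate ids rejected
  expect_error(distance_matrix(list(base, base)), "duplicate model ids")
})

test_that("top split recovers planted clusters and is deterministic on ties", {
  base <- generate_toy_gem(3, seed = 9)$model
  ens <- generate_ensemble(base, n_models = 16, n_variable_reactions = 20,
                           separation = 12, noise = 0, seed = 9)
  D <- distance_matrix(ens$models)
  split <- top_split_clusters(D)
  expect_equal(ari(split$labels, ens$truth$model_cluster_labels[names(split$labels)]), 1.0)
  # degenerate all-zero matrix: a deterministic 2-partition
  D0 <- matrix(0L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  s1 <- top_split_clusters(D0)
  s2 <- top_split_clusters(D0)
  expect_identical(s1$labels, s2$labels)
  expect_setequal(unique(s1$labels), 1:2)
})

test_that("merging is order-invariant and unions all components", {
  base <- generate_toy_gem(2, seed = 10)$model
  ens <- generate_ensemble(base, n_models = 6, n_variable_reactions = 10,
                           separation = 5, noise = 0.3, seed = 10)
  merged <- merge_models(ens$models)
  set.seed(1)
  merged_perm <- merge_models(sample(ens$models))
  expect_identical(merged$stoich, merged_perm$stoich)
  expect_identical(merged$rxns, merged_perm$rxns)
  # every member's reactions are contained
  for (m in ens$models)
    expect_true(all(model_reactions(m) %in% model_reactions(merged)))
  # merge of one model is the identity
  expect_identical(merge_models(ens$models[1]), ens$models[[1]])
})

test_that("merged growth dominates every member's growth", {
  for (seed in c(3, 4)) {
    base <- generate_toy_gem(2, seed = seed)$model
    ens <- generate_ensemble(base, n_models = 5, n_variable_reactions = 8,
                             separation = 4, noise = 0.3, seed = seed)
    merged <- merge_models(ens$models)
    g <- fba(merged)$objective_value
    for (m in ens$models)
      expect_gte(g + 1e-8, fba(m)$objective_value)
  }
})

test_that("merge rejects conflicting stoichiometry and resolves objectives", {
  m1 <- make_chain_model()
  m2 <- make_chain_model()
  m2$id <- "chain2"
  m2$stoich$R1 <- c(A = -2, B = 1)
  expect_error(merge_models(list(m1, m2)), "R1")
  # disjoint single-pathway models: both pathways present after merge; the
  # minority objective id is kept as an ordinary reaction, with a warning
  t1 <- generate_toy_gem(1, seed = 61)$model; t1$id <- "t1"
  t1b <- t1; t1b$id <- "t1b"
  t2 <- generate_toy_gem(1, seed = 62)$model; t2$id <- "t2"
  ren <- function(x) sub("P1", "Q1", x, fixed = TRUE)
  t2$mets$id <- ren(t2$mets$id); t2$mets$name <- t2$mets$id
  t2$rxns$id <- ren(t2$rxns$id)
  t2$rxns$id[t2$rxns$id == "BIOMASS"] <- "BIOMASS_Q"
  t2$stoich <- lapply(t2$stoich, function(s) setNames(s, ren(names(s))))
  names(t2$stoich) <- t2$rxns$id
  t2$rxns$gpr <- sub("g_P1", "g_Q1", t2$rxns$gpr, fixed = TRUE)
  t2 <- gem(t2$id, t2$mets, t2$rxns, t2$stoich, "BIOMASS_Q")
  expect_warning(merged <- merge_models(list(t1, t1b, t2)),
                 "objectives disagree")
  expect_equal(merged$objective, "BIOMASS")
  expect_true(all(model_reactions(t1) %in% model_reactions(merged)))
  expect_true(all(model_reactions(t2) %in% model_reactions(merged)))
})

test_that("shared-reaction GPRs merge as an OR across member rules", {
  m1 <- make_chain_model(gpr_chain = "g1")
  m2 <- make_chain_model(gpr_chain = "g2"); m2$id <- "c2"
  merged <- merge_models(list(m1, m2))
  dnf <- gpr_to_dnf(merged$rxns$gpr[merged$rxns$id == "R1"])
  expect_setequal(vapply(dnf, paste, character(1), collapse = "+"), c("g1", "g2"))
  # deduplication: identical rules collapse
  m3 <- make_chain_model(gpr_chain = "g1"); m3$id <- "c3"
  merged2 <- merge_models(list(m1, m3))
  expect_equal(merged2$rxns$gpr[merged2$rxns$id == "R1"], "g1")
})

test_that("cluster survival comparison joins labels to the clinical table", {
  labels <- setNames(c(1L, 1L, 2L, 2L), paste0("s", 1:4))
  clin <- data.frame(sample_id = paste0("s", 1:4), vital_status = "dead",
                     days = c(100, 200, 400, 600))
  cs <- cluster_survival_test(labels, clin)
  expect_equal(cs$mean_cluster1, 150)
  expect_equal(cs$mean_cluster2, 500)
  expect_s3_class(cs$test, "htest")
})
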