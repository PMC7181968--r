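test_that("logic transformation gives every reaction a single label", {
  toy <- generate_toy_gem(3, gpr_mix = c(single = 0.3, or = 0.4, and = 0.3),
                          seed = 17)
  ltm <- logic_transform(toy$model)
  # each reaction's rule is a bare label (no operators)
  expect_false(any(grepl(" and | or ", ltm$rxns$gpr)))
  # OR rules expand into per-disjunct duplicates plus a drain
  or_rxns <- toy$model$rxns$id[grepl(" or ", toy$model$rxns$gpr)]
  for (rid in or_rxns) {
    expect_true(paste0("ltmdrain__", rid) %in% ltm$rxns$id)
    expect_true(all(paste0(rid, "__dnf", 1:2) %in% ltm$rxns$id))
  }
  # AND rules collapse to one composite pseudo-gene
  and_rxns <- toy$model$rxns$id[grepl(" and ", toy$model$rxns$gpr)]
  for (rid in and_rxns) {
    lab <- ltm$rxns$gpr[ltm$rxns$id == rid]
    expect_true(lab %in% names(ltm$pseudo_genes))
    expect_setequal(ltm$pseudo_genes[[lab]],
                    gpr_genes(toy$model$rxns$gpr[toy$model$rxns$id == rid]))
  }
  # mappings recover every original gene
  mapped <- unique(c(unlist(ltm$pseudo_genes),
                     ltm$rxns$gpr[!ltm$rxns$gpr %in% names(ltm$pseudo_genes)]))
  expect_true(all(model_genes(toy$model) %in% mapped))
})

test_that("logic transformation preserves the wild-type optimum", {
  for (toy in random_toy_models(6, seed_base = 200L)) {
    wt <- fba(toy$model)$objective_value
    expect_equal(fba(logic_transform(toy$model))$objective_value, wt,
                 tolerance = 1e-6, info = toy$model$id)
  }
})

test_that("LTM and direct knockout routes agree for every gene", {
  for (toy in random_toy_models(4, seed_base = 300L)) {
    direct <- essential_genes(toy$model, method = "direct")
    via_ltm <- essential_genes(toy$model, method = "ltm")
    expect_equal(via_ltm$ko_growth, direct$ko_growth, tolerance = 1e-6,
                 info = toy$model$id)
    expect_identical(via_ltm$essential, direct$essential)
  }
})

test_that("an oversized DNF falls back to direct rule evaluation", {
  big <- paste(sprintf("(a%d or b%d)", 1:8, 1:8), collapse = " and ")
  m <- make_chain_model(gpr_chain = big)
  expect_warning(ltm <- logic_transform(m, max_disjuncts = 64), "disjuncts")
  expect_equal(ltm$fallback, "R1")
  # the fallback route still agrees with direct per-gene knockouts: every OR
  # pair has an isozyme partner, so no single gene is essential
  ess <- suppressWarnings(essential_genes(m, method = "ltm"))
  direct <- essential_genes(m, method = "direct")
  expect_equal(ess$ko_growth, direct$ko_growth, tolerance = 1e-6)
  expect_false(any(ess$essential))
  # but knocking out a whole OR pair severs the chain on both routes
  expect_equal(fba(set_bounds(ltm, ltm_dead <- gemscreen:::ltm_disabled_reactions(
    ltm, "a1"), 0, 0))$objective_value,
    fba(apply_knockout(m, "a1"))$objective_value, tolerance = 1e-6)
  expect_equal(fba(apply_knockout(m, c("a1", "b1")))$objective_value, 0)
})

test_that("essentiality recovers the planted truth exactly", {
  mixes <- list(c(single = 1, or = 0, and = 0),
                c(single = 0, or = 1, and = 0),
                c(single = 0, or = 0, and = 1),
                c(single = 0.4, or = 0.3, and = 0.3))
  for (i in seq_along(mixes)) {
    toy <- generate_toy_gem(3, gpr_mix = mixes[[i]], seed = 400 + i)
    res <- essential_genes(toy$model)
    found <- res$gene[res$essential]
    expect_setequal(found, toy$truth$essential_genes)
    expect_setequal(res$gene, toy$truth$all_genes)
  }
})

test_that("sole-pathway genes are essential, isozyme pairs are not", {
  expect_true(essential_genes(make_chain_model(gpr_chain = "g1"))$essential)
  res <- essential_genes(make_parallel_model())
  expect_false(any(res$essential))
})

test_that("growth ratios are bounded and essentiality is monotone in threshold", {
  toy <- generate_toy_gem(3, seed = 51)
  res <- essential_genes(toy$model, threshold = 1e-3)
  expect_true(all(res$growth_ratio >= 0 & res$growth_ratio <= 1 + 1e-6))
  loose <- essential_genes(toy$model, threshold = 0.5)
  expect_true(all(res$gene[res$essential] %in% loose$gene[loose$essential]))
})

test_that("essentiality errors on zero wild-type growth", {
  m <- make_chain_model(uptake = 0)
  expect_error(essential_genes(m), "zero")
})

test_that("consensus fractions tally per-model essentiality", {
  toy <- generate_toy_gem(2, gpr_mix = c(single = 1, or = 0, and = 0), seed = 71)
  m1 <- toy$model
  # single-model ensemble: fractions in {0,1}, equal to its own result
  cons1 <- consensus_essentiality(list(m1))
  own <- essential_genes(m1)
  expect_setequal(cons1$consensus, own$gene[own$essential])
  expect_true(all(cons1$per_gene$fraction %in% c(0, 1)))

  # gene absent from one of two models: fraction 0.5, fraction_present 1
  m2 <- generate_toy_gem(1, gpr_mix = c(single = 1, or = 0, and = 0),
                         seed = 71)$model
  m2$id <- "small"
  cons <- consensus_essentiality(list(m1, m2))
  only_m1 <- setdiff(model_genes(m1), model_genes(m2))
  row <- cons$per_gene[cons$per_gene$gene == only_m1[1], ]
  expect_equal(row$fraction, 0.5)
  expect_equal(row$n_present, 1)
  expect_equal(row$fraction_present, 1)
})

test_that("merged-model essentiality is inherited by every member", {
  base <- generate_toy_gem(3, seed = 81)$model
  ens <- generate_ensemble(base, n_models = 6, n_variable_reactions = 10,
                           separation = 5, noise = 0.2, seed = 81)
  merged <- merge_models(ens$models)
  merged_ess <- essential_genes(merged)
  cons <- consensus_essentiality(ens$models)
  for (g in merged_ess$gene[merged_ess$essential]) {
    expect_equal(cons$per_gene$fraction[cons$per_gene$gene == g], 1, info = g)
  }
})
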