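test_that("the default currency list has 20 entries and matching is robust", {
  expect_length(currency_metabolites(), 20)
  m <- gem("cur",
           metabolites = data.frame(
             id = c("atp_c", "adp_c", "A", "B"),
             name = c("ATP", "ADP", "A", "B"),
             compartment = "c"),
           reactions = data.frame(id = c("EX", "R", "BIO"),
                                  lb = 0, ub = c(10, 10, 10),
                                  gpr = c("", "g1", "")),
           stoichiometry = list(EX = c(A = 1),
                                R = c(A = -1, atp_c = -1, B = 1, adp_c = 1),
                                BIO = c(B = -1)),
           objective = "BIO")
  g <- build_graph(m, remove_currency = TRUE)
  # after removal, g1 touches only A and B
  expect_setequal(g$metabolites, c("A", "B"))
  expect_equal(g$met_genes$A, "g1")
  expect_equal(g$met_genes$B, "g1")
  # without removal, cofactors stay in
  g2 <- build_graph(m, remove_currency = FALSE)
  expect_true(all(c("atp_c", "adp_c") %in% g2$metabolites))
  # a model without currency metabolites is unchanged by removal
  toy <- generate_toy_gem(2, seed = 14)$model
  expect_identical(build_graph(toy, TRUE)$met_genes,
                   build_graph(toy, FALSE)$met_genes)
})

test_that("gene_z matches the normal-quantile oracle and is antisymmetric", {
  # one-directional p = 0.05 => z ~ 1.6449
  expect_equal(gene_z(0.1, up = TRUE, direction = "up"),
               qnorm(1 - 0.05), tolerance = 1e-6)
  expect_equal(gene_z(0.1, up = TRUE, direction = "up"), 1.6449, tolerance = 1e-4)
  # monotone: smaller p, larger aligned z
  ps <- c(0.001, 0.01, 0.1, 0.5, 0.99)
  zs <- gene_z(ps, up = rep(TRUE, 5), direction = "up")
  expect_true(all(diff(zs) < 0))
  # up-run and down-run z for the same gene sum to ~0
  z_up <- gene_z(0.04, up = TRUE, direction = "up")
  z_dn <- gene_z(0.04, up = TRUE, direction = "down")
  expect_equal(z_up + z_dn, 0, tolerance = 1e-9)
  expect_error(gene_z(0, up = TRUE), "p-values")
  expect_error(gene_z(1.2, up = TRUE), "p-values")
})

test_that("a single-neighbor metabolite on a null background scores its gene z", {
  pool_genes <- sprintf("null_%03d", 1:400)
  graph <- make_null_graph(80, pool_genes, k_range = 1, seed = 2)
  set.seed(3)
  scores <- data.frame(gene = pool_genes,
                       log2fc = -1,  # all "up in low"
                       p = runif(400))
  scores$p[scores$gene == graph$met_genes[[1]]] <- 0.05
  res <- reporter_metabolites(graph, scores, n_background = 10000, seed = 4)
  row <- res$up[res$up$metabolite == graph$metabolites[1], ]
  # directional p = 0.025 => raw z ~ 1.96; null background is ~N(0,1)
  expect_equal(row$z_raw, qnorm(1 - 0.025), tolerance = 1e-6)
  expect_equal(row$z_corr, qnorm(1 - 0.025), tolerance = 0.15)
})

test_that("reporter ranking is invariant to gene input order and seed-stable", {
  genes <- sprintf("g%03d", 1:100)
  graph <- make_null_graph(40, genes, seed = 5)
  set.seed(6)
  scores <- data.frame(gene = genes, log2fc = sample(c(-1, 1), 100, TRUE),
                       p = runif(100))
  r1 <- reporter_metabolites(graph, scores, n_background = 2000, seed = 9)
  r2 <- reporter_metabolites(graph, scores[sample(100), ], n_background = 2000,
                             seed = 9)
  expect_identical(r1$up, r2$up)
  expect_identical(r1$down, r2$down)
})

test_that("a planted high-significance metabolite ranks first", {
  genes <- sprintf("g%04d", 1:300)
  graph <- make_null_graph(199, genes, k_range = 3:6, seed = 7)
  planted_genes <- sort(sample(genes, 5))
  graph$met_genes[["met_planted"]] <- planted_genes
  graph$metabolites <- c(graph$metabolites, "met_planted")
  set.seed(8)
  scores <- data.frame(gene = genes, log2fc = -1, p = runif(300))
  scores$p[scores$gene %in% planted_genes] <- 0.001
  res <- reporter_metabolites(graph, scores, n_background = 10000, seed = 10)
  expect_equal(res$up$metabolite[1], "met_planted")
  expect_equal(nrow(res$up), 200)
})

test_that("currency removal changes adjacency only, not surviving gene scores", {
  m <- generate_toy_gem(3, seed = 44)$model
  # tag one metabolite as water
  m$mets$name[3] <- "H2O"
  g_with <- build_graph(m, remove_currency = FALSE)
  g_without <- build_graph(m, remove_currency = TRUE)
  set.seed(2)
  scores <- data.frame(gene = model_genes(m), log2fc = -1,
                       p = runif(length(model_genes(m))))
  r_with <- reporter_metabolites(g_with, scores, n_background = 3000, seed = 3)
  r_without <- reporter_metabolites(g_without, scores, n_background = 3000, seed = 3)
  shared <- intersect(r_with$up$metabolite, r_without$up$metabolite)
  a <- r_with$up[match(shared, r_with$up$metabolite), c("metabolite", "k", "z_raw")]
  b <- r_without$up[match(shared, r_without$up$metabolite), c("metabolite", "k", "z_raw")]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("subnetwork search returns a connected high-scoring neighborhood", {
  # a star: one metabolite joining the top-z genes
  star_genes <- paste0("s", 1:4)
  other <- paste0("o", 1:6)
  graph <- structure(list(
    met_genes = c(list(hub = star_genes),
                  setNames(lapply(other, identity), paste0("m_", other))),
    genes = sort(c(star_genes, other)),
    metabolites = c("hub", paste0("m_", other)),
    currency_removed = FALSE), class = "gene_met_graph")
  z <- setNames(c(rep(3, 4), rep(-1, 6)), c(star_genes, other))
  sub <- reporter_subnetwork(graph, z, size_budget = 6, seed = 1)
  expect_setequal(sub$genes, star_genes)
  expect_true("hub" %in% sub$metabolites)
  expect_equal(metabolite_gene_degree(sub, "hub"), 4)
  expect_error(metabolite_gene_degree(sub, "nope"), "not in subnetwork")
  # budget 1: the single best gene with its metabolite
  sub1 <- reporter_subnetwork(graph, z, size_budget = 1, seed = 1)
  expect_length(sub1$genes, 1)
  expect_true(sub1$genes %in% star_genes)
  expect_gte(length(sub1$metabolites), 1)
})

test_that("subnetwork degree is bounded by the full-graph degree", {
  genes <- sprintf("g%03d", 1:60)
  graph <- make_null_graph(30, genes, k_range = 2:5, seed = 21)
  set.seed(22)
  z <- setNames(rnorm(60), genes)
  sub <- reporter_subnetwork(graph, z, size_budget = 10, seed = 23)
  for (met in sub$metabolites) {
    expect_lte(metabolite_gene_degree(sub, met), length(graph$met_genes[[met]]))
    # brute-force recount
    expect_equal(metabolite_gene_degree(sub, met),
                 length(intersect(graph$met_genes[[met]], sub$genes)))
  }
})

test_that("a planted connected high-z cluster is recovered", {
  # ring of metabolites linking 8 planted genes, plus null satellites
  planted <- paste0("p", 1:8)
  met_genes <- list()
  for (i in 1:8) {
    met_genes[[paste0("link_", i)]] <-
      c(planted[i], planted[1 + i %% 8])
  }
  null_genes <- paste0("n", 1:40)
  for (j in seq_along(null_genes))
    met_genes[[paste0("sat_", j)]] <- null_genes[j]
  graph <- structure(list(met_genes = met_genes,
                          genes = sort(c(planted, null_genes)),
                          metabolites = names(met_genes),
                          currency_removed = FALSE),
                     class = "gene_met_graph")
  set.seed(30)
  z <- setNames(c(rep(2.5, 8), rnorm(40)), c(planted, null_genes))
  recalls <- vapply(1:20, function(s) {
    sub <- reporter_subnetwork(graph, z, size_budget = 8, seed = s)
    mean(planted %in% sub$genes)
  }, numeric(1))
  expect_gte(mean(recalls), 0.9)
})
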