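# Small fixtures built in code.

# linear chain: exchange (ub = uptake) -> A -> biomass (ub = cap)
make_chain_model <- function(uptake = 10, cap = 5, gpr_chain = "") {
  gem(id = "chain",
      metabolites = data.frame(id = c("A", "B"), compartment = "c",
                               stringsAsFactors = FALSE),
      reactions = data.frame(id = c("EX_A", "R1", "BIOMASS"),
                             lb = 0, ub = c(uptake, 1000, cap),
                             gpr = c("", gpr_chain, ""),
                             stringsAsFactors = FALSE),
      stoichiometry = list(EX_A = c(A = 1), R1 = c(A = -1, B = 1),
                           BIOMASS = c(B = -1)),
      objective = "BIOMASS")
}

# two parallel isozyme routes A -> B, then biomass
make_parallel_model <- function() {
  gem(id = "parallel",
      metabolites = data.frame(id = c("A", "B"), compartment = "c",
                               stringsAsFactors = FALSE),
      reactions = data.frame(id = c("EX_A", "R1a", "R1b", "BIOMASS"),
                             lb = 0, ub = c(10, 1000, 1000, 1000),
                             gpr = c("", "g1", "g2", ""),
                             stringsAsFactors = FALSE),
      stoichiometry = list(EX_A = c(A = 1), R1a = c(A = -1, B = 1),
                           R1b = c(A = -1, B = 1), BIOMASS = c(B = -1)),
      objective = "BIOMASS")
}

# synthetic gene-metabolite graph assembled directly (no model needed):
# each metabolite draws k neighbor genes from the pool
make_null_graph <- function(n_mets, gene_pool, k_range = 1:8, seed = 1L) {
  set.seed(seed)
  met_ids <- sprintf("met_%03d", seq_len(n_mets))
  met_genes <- lapply(met_ids, function(m)
    sort(sample(gene_pool, sample(k_range, 1))))
  names(met_genes) <- met_ids
  structure(list(met_genes = met_genes,
                 genes = sort(unique(unlist(met_genes))),
                 metabolites = met_ids,
                 currency_removed = FALSE),
            class = "gene_met_graph")
}

random_toy_models <- function(n, seed_base = 100L) {
  lapply(seq_len(n), function(i) {
    generate_toy_gem(n_pathways = 2 + (i %% 3),
                     gpr_mix = c(single = 0.4, or = 0.3, and = 0.3),
                     seed = seed_base + i)
  })
}
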