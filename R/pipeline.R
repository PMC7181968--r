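#' Default pipeline configuration
#'
#' Every tunable the pipeline stages expose, with its documented default.
#' Unknown keys passed to [simulate_bundle()] or [run_pipeline()] are
#' rejected before any stage runs.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,                      # master seed; per-stage seeds derive from it
    # synthetic bundle geometry
    n_pathways = 4L,
    gpr_mix = c(single = 0.5, or = 0.25, and = 0.25),
    n_models = 30L,
    n_variable_reactions = 20L,
    separation = 10L,
    ensemble_noise = 0.05,
    n_genes = 400L,
    n_samples = 90L,
    surv_median_days = 350,
    de_effect = 2,
    n_de_up = 25L,
    n_de_down = 25L,
    block_sizes = c(6L, 8L, 10L),
    block_rho = 0.995,
    n_tasks = 12L,
    n_infeasible = 3L,
    n_cell_lines = 31L,
    dependency_sd = 0.1,
    n_shared_pathways = 2L,
    n_tumor_private_pathways = 2L,
    n_healthy_private_pathways = 1L,
    # analysis tunables
    alpha = 0.05,
    de_orientation = "high_vs_low",
    corr_cutoff = 0.99,
    corr_mode = "threshold",
    walk_length = 4,
    min_cluster_size = 5,
    min_cluster_corr = 0.5,
    linkage = "complete",
    essential_threshold = 1e-3,
    ko_method = "ltm",
    coupling = "knockout",
    n_background = 10000L,
    subnet_budget = 20L
  )
}

merge_config <- function(config) {
  base <- default_config()
  if (is.null(config)) return(base)
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  base[names(config)] <- config
  base
}

stage_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 97L + offset * 1009L) %% 2147483647)
}

#' Generate the full synthetic input bundle
#'
#' Invokes every generator with seeds derived from the master seed and
#' writes the bundle — tumor/healthy models, ensemble members, expression
#' and clinical tables, task battery, dependency scores, and the planted
#' truth — under \code{dir}. Two calls with the same configuration produce
#' identical bundles.
#'
#' @param config Named list overriding [default_config()] entries.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory bundle components and
#'   \code{truth}.
#' @export
simulate_bundle <- function(config = list(), dir = NULL) {
  cfg <- merge_config(config)
  scen <- generate_screen_scenario(
    n_shared = cfg$n_shared_pathways,
    n_tumor_private = cfg$n_tumor_private_pathways,
    n_healthy_private = cfg$n_healthy_private_pathways,
    gpr_mix = cfg$gpr_mix,
    seed = stage_seed(cfg$seed, 1L))
  ens <- generate_ensemble(scen$tumor,
                           n_models = cfg$n_models,
                           n_variable_reactions = cfg$n_variable_reactions,
                           separation = cfg$separation,
                           noise = cfg$ensemble_noise,
                           seed = stage_seed(cfg$seed, 2L))
  expr <- generate_expression(cfg$n_genes, cfg$n_samples,
                              surv_median_days = cfg$surv_median_days,
                              de_effect = cfg$de_effect,
                              n_de_up = cfg$n_de_up, n_de_down = cfg$n_de_down,
                              block_sizes = cfg$block_sizes,
                              block_rho = cfg$block_rho,
                              seed = stage_seed(cfg$seed, 3L))
  tumor_tasks <- generate_tasks(scen$tumor, cfg$n_tasks, cfg$n_infeasible,
                                seed = stage_seed(cfg$seed, 4L))
  # name the tail (plain-noise) expression genes after the model's genes so
  # the DE table covers the metabolic network for reporter scoring
  mg <- model_genes(scen$tumor)
  n_reserved <- sum(cfg$block_sizes) + cfg$n_de_up + cfg$n_de_down
  if (n_reserved + length(mg) > cfg$n_genes)
    stop("n_genes too small to host blocks, DE plants, and model genes")
  rownames(expr$expression)[(cfg$n_genes - length(mg) + 1L):cfg$n_genes] <- mg
  dep <- generate_dependency_matrix(
    scen$truth$essential_genes, cfg$n_cell_lines,
    essential_genes = scen$truth$nontoxic_essential,
    sd = cfg$dependency_sd, seed = stage_seed(cfg$seed, 5L))

  truth <- c(scen$truth["essential_genes"], scen$truth["toxic_genes"],
             scen$truth["nontoxic_essential"],
             list(model_cluster_labels = as.list(ens$truth$model_cluster_labels)),
             expr$truth["de_genes_up"], expr$truth["de_genes_down"],
             expr$truth["coexpr_blocks"],
             list(task_feasible = as.list(tumor_tasks$truth$feasible),
                  seed = cfg$seed))

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "ensemble"), showWarnings = FALSE)
    write_gem_tabular(scen$tumor, file.path(dir, "tumor.tsv"))
    write_gem_tabular(scen$healthy, file.path(dir, "healthy.tsv"))
    for (m in ens$models)
      write_gem_tabular(m, file.path(dir, "ensemble", paste0(m$id, ".tsv")))
    utils::write.table(data.frame(gene = rownames(expr$expression),
                                  expr$expression, check.names = FALSE),
                       file.path(dir, "expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(expr$clinical, file.path(dir, "clinical.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_tasks(scen$tasks, file.path(dir, "healthy_tasks.tsv"))
    write_tasks(tumor_tasks$tasks, file.path(dir, "tumor_tasks.tsv"))
    utils::write.table(data.frame(gene = rownames(dep), dep, check.names = FALSE),
                       file.path(dir, "dependency.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_truth(truth, file.path(dir, "truth.json"))
    jsonlite::write_json(cfg, file.path(dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(tumor = scen$tumor, healthy = scen$healthy,
                 models = ens$models, expression = expr$expression,
                 clinical = expr$clinical, tasks = scen$tasks,
                 tumor_tasks = tumor_tasks$tasks,
                 dependency = dep, truth = truth, config = cfg))
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the stages in dependency order on an in-memory bundle (as
#' returned by [simulate_bundle()]): survival stratification and two-group
#' differential expression; co-expression network, communities and cluster
#' filters; ensemble distance matrix, top-split clustering and merge;
#' essentiality on the merged model and consensus across members; healthy
#' task toxicity screen and target shortlist; reporter metabolites and
#' subnetwork; dependency-score validation of the shortlist. When
#' \code{out_dir} is given, each stage writes its typed outputs plus a
#' machine-readable manifest (stage, input checksums, seed, runtime).
#'
#' @param bundle Bundle list from [simulate_bundle()] (or assembled by hand
#'   with the same element names).
#' @param config Named list overriding [default_config()] entries.
#' @param out_dir Optional output directory.
#' @return List with the results of every stage.
#' @export
run_pipeline <- function(bundle, config = list(), out_dir = NULL) {
  cfg <- merge_config(config)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  emit <- function(stage, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    files <- writer(out_dir)
    manifest[[stage]] <<- list(
      stage = stage,
      outputs = as.list(stats::setNames(
        unname(tools::md5sum(file.path(out_dir, files))), files)),
      seed = cfg$seed,
      runtime_s = round(proc.time()[["elapsed"]] - t0, 4))
    invisible(NULL)
  }

  strat <- stratify_survival(bundle$clinical)
  de <- simple_de(bundle$expression, strat$low, strat$high)
  de_split <- split_de(de, alpha = cfg$alpha, orientation = cfg$de_orientation)
  emit("cohort", function(d) {
    utils::write.table(de, file.path(d, "de.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_gene_list(de_split$up_in_low, file.path(d, "genes_up_in_low.txt"))
    write_gene_list(de_split$down_in_low, file.path(d, "genes_down_in_low.txt"))
    c("de.tsv", "genes_up_in_low.txt", "genes_down_in_low.txt")
  })

  cm <- correlation_matrix(log2(bundle$expression))
  net <- build_network(cm, cutoff = cfg$corr_cutoff, mode = cfg$corr_mode)
  comm <- walktrap_communities(net, walk_length = cfg$walk_length)
  clusters <- filter_clusters(comm, cm, min_size = cfg$min_cluster_size,
                              min_corr = cfg$min_cluster_corr)
  emit("coexpression", function(d) {
    write_network(net, file.path(d, "network.graphml"))
    write_clusters(clusters, file.path(d, "clusters.tsv"))
    c("network.graphml", "clusters.tsv")
  })

  D <- distance_matrix(bundle$models)
  split <- top_split_clusters(D, linkage = cfg$linkage)
  merged <- merge_models(bundle$models)
  emit("ensemble", function(d) {
    write_distance_matrix(D, file.path(d, "distance_matrix.tsv"))
    utils::write.table(data.frame(model = names(split$labels),
                                  cluster = unname(split$labels)),
                       file.path(d, "clusters_models.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_gem_sbml(merged, file.path(d, "merged.xml"))
    c("distance_matrix.tsv", "clusters_models.tsv", "merged.xml")
  })

  ess <- essential_genes(merged, threshold = cfg$essential_threshold,
                         method = cfg$ko_method)
  cons <- consensus_essentiality(bundle$models,
                                 threshold = cfg$essential_threshold,
                                 method = cfg$ko_method)
  emit("essentiality", function(d) {
    write_essentiality(ess, file.path(d, "essentiality.tsv"))
    utils::write.table(cons$per_gene, file.path(d, "consensus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    c("essentiality.tsv", "consensus.tsv")
  })

  report <- toxicity_screen(bundle$healthy, bundle$tasks,
                            candidates = ess$gene[ess$essential],
                            coupling = cfg$coupling)
  shortlist <- shortlist_targets(ess, report)
  emit("toxicity", function(d) {
    write_toxicity_report(report, file.path(d, "toxicity.tsv"))
    write_gene_list(shortlist, file.path(d, "shortlist.txt"))
    c("toxicity.tsv", "shortlist.txt")
  })

  graph <- build_graph(merged)
  rep_scores <- reporter_metabolites(graph, de,
                                     orientation = cfg$de_orientation,
                                     n_background = cfg$n_background,
                                     seed = stage_seed(cfg$seed, 11L))
  emit("reporter", function(d) {
    write_reporter_scores(rep_scores, file.path(d, "reporter.tsv"))
    "reporter.tsv"
  })

  validation <- if (length(shortlist) && !is.null(bundle$dependency))
    dependency_validation(bundle$dependency,
                          intersect(shortlist, rownames(bundle$dependency)))
  else NULL
  if (!is.null(validation))
    emit("validation", function(d) {
      utils::write.table(validation, file.path(d, "dependency_validation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      "dependency_validation.tsv"
    })

  if (!is.null(out_dir)) {
    jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(stratification = strat, de = de, de_split = de_split,
       correlation = cm, network = net, communities = comm,
       clusters = clusters, distance = D, model_split = split,
       merged = merged, essentiality = ess, consensus = cons,
       toxicity = report, shortlist = shortlist,
       reporter = rep_scores, validation = validation,
       config = cfg)
}
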