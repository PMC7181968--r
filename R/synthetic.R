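#' Synthetic inputs with planted ground truth
#'
#' Every input the pipeline consumes — toy genome-scale models, model
#' ensembles with planted cluster structure, expression matrices with planted
#' survival-associated differential expression and co-expression blocks,
#' metabolic task batteries, and gene dependency score matrices — can be
#' generated here, with the planted truth recorded so downstream stages are
#' testable without external downloads. All generators are deterministic
#' given their seed.
#'
#' @name synthetic_data
NULL

# descriptor for one linear pathway: exchange -> M0 -> M1 ... -> ML,
# each chain step carrying a single/OR/AND gene rule
make_pathway_spec <- function(name, chain_length, gpr_types) {
  mets <- paste0(name, "_M", 0:chain_length)
  rxns <- paste0(name, "_R", seq_len(chain_length))
  genes_essential <- character()
  genes_all <- character()
  gprs <- character(chain_length)
  for (k in seq_len(chain_length)) {
    g <- paste0("g_", name, "_", k)
    gprs[k] <- switch(gpr_types[k],
      single = { genes_essential <- c(genes_essential, g); genes_all <- c(genes_all, g); g },
      or = {
        gs <- paste0(g, c("a", "b")); genes_all <- c(genes_all, gs)
        paste(gs, collapse = " or ")
      },
      and = {
        gs <- paste0(g, c("a", "b"))
        genes_essential <- c(genes_essential, gs); genes_all <- c(genes_all, gs)
        paste(gs, collapse = " and ")
      })
  }
  list(name = name, mets = mets, rxns = rxns, exchange = paste0("EX_", name),
       gprs = gprs, genes_essential = genes_essential, genes_all = genes_all)
}

# assemble a gem from pathway descriptors: per-pathway exchange and chain,
# one biomass reaction consuming each pathway's terminal metabolite
build_pathway_model <- function(id, pathway_specs, uptake = 10) {
  met_ids <- unlist(lapply(pathway_specs, `[[`, "mets"))
  rx <- data.frame(id = character(), lb = numeric(), ub = numeric(),
                   gpr = character(), stringsAsFactors = FALSE)
  stoich <- list()
  for (pw in pathway_specs) {
    rx <- rbind(rx, data.frame(id = pw$exchange, lb = 0, ub = uptake, gpr = "",
                               stringsAsFactors = FALSE))
    stoich[[pw$exchange]] <- stats::setNames(1, pw$mets[1])
    for (k in seq_along(pw$rxns)) {
      rx <- rbind(rx, data.frame(id = pw$rxns[k], lb = 0, ub = 1000,
                                 gpr = pw$gprs[k], stringsAsFactors = FALSE))
      stoich[[pw$rxns[k]]] <- stats::setNames(c(-1, 1), pw$mets[k + c(0, 1)])
    }
  }
  rx <- rbind(rx, data.frame(id = "BIOMASS", lb = 0, ub = 1000, gpr = "",
                             stringsAsFactors = FALSE))
  stoich[["BIOMASS"]] <- stats::setNames(
    rep(-1, length(pathway_specs)),
    vapply(pathway_specs, function(pw) pw$mets[length(pw$mets)], character(1)))
  m <- gem(id = id,
           metabolites = data.frame(id = met_ids, compartment = "c",
                                    stringsAsFactors = FALSE),
           reactions = rx, stoichiometry = stoich, objective = "BIOMASS")
  attr(m, "pathways") <- pathway_specs
  m
}

#' Generate a toy genome-scale model with known essential genes
#'
#' Builds \code{n_pathways} independent linear pathways, each fed by an
#' exchange reaction (uptake bound 10) and ending in a precursor consumed by
#' a single biomass reaction. Chain reactions get a single-gene, OR-isozyme,
#' or AND-complex rule drawn from \code{gpr_mix}. Ground-truth essential
#' genes are known by construction: every single-rule gene and every AND
#' constituent severs its pathway when knocked out (and every pathway feeds
#' biomass), while OR isozymes leave a parallel route.
#'
#' @param n_pathways Number of pathways (>= 1).
#' @param gpr_mix Named proportions for rule types \code{single}, \code{or},
#'   \code{and}.
#' @param chain_length Range (min, max) of reactions per pathway.
#' @param seed Integer seed.
#' @return List with \code{model} (a \code{gem}) and \code{truth} (fields
#'   \code{essential_genes}, \code{all_genes}, \code{seed}).
#' @export
generate_toy_gem <- function(n_pathways, gpr_mix = c(single = 0.5, or = 0.25, and = 0.25),
                             chain_length = c(2L, 4L), seed = 1L) {
  stopifnot(n_pathways >= 1)
  gpr_mix <- gpr_mix / sum(gpr_mix)
  set.seed(seed)
  specs <- lapply(seq_len(n_pathways), function(p) {
    len <- sample(chain_length[1]:chain_length[2], 1)
    types <- sample(names(gpr_mix), len, replace = TRUE, prob = gpr_mix)
    make_pathway_spec(paste0("P", p), len, types)
  })
  model <- build_pathway_model(paste0("toy", seed), specs)
  truth <- list(
    essential_genes = sort(unlist(lapply(specs, `[[`, "genes_essential"))),
    all_genes = sort(unlist(lapply(specs, `[[`, "genes_all"))),
    seed = seed)
  list(model = model, truth = truth)
}

#' Generate a model ensemble with planted two-cluster structure
#'
#' Adds \code{n_variable_reactions} dispensable side reactions to the base
#' model (each diverts a chain metabolite into a dead-end sink metabolite, so
#' presence or absence never changes growth), defines two archetype
#' presence/absence vectors differing in \code{separation} of them, and draws
#' each member model from one archetype with independent per-reaction flips
#' at rate \code{noise}. Cluster labels are recorded as ground truth.
#'
#' @param base A \code{gem} from [generate_toy_gem()].
#' @param n_models Ensemble size.
#' @param n_variable_reactions Number of variable (dispensable) reactions.
#' @param separation Number of variable reactions differing between
#'   archetypes (<= \code{n_variable_reactions}).
#' @param noise Per-reaction flip probability.
#' @param seed Integer seed.
#' @return List with \code{models} (list of \code{gem}) and \code{truth}
#'   (fields \code{model_cluster_labels}, \code{variable_reactions},
#'   \code{archetypes}, \code{seed}).
#' @export
generate_ensemble <- function(base, n_models, n_variable_reactions = 20L,
                              separation = 10L, noise = 0.05, seed = 1L) {
  stopifnot(separation <= n_variable_reactions, n_models >= 1)
  pathways <- attr(base, "pathways")
  if (is.null(pathways))
    stop("base model lacks pathway annotation; use generate_toy_gem()")
  set.seed(seed)
  # dead-end diversion reactions off pathway metabolites
  var_ids <- paste0("VAR_", seq_len(n_variable_reactions))
  var_stoich <- vector("list", n_variable_reactions)
  ext_mets <- paste0("VX_", seq_len(n_variable_reactions))
  for (j in seq_len(n_variable_reactions)) {
    pw <- pathways[[1 + (j - 1) %% length(pathways)]]
    src <- pw$mets[length(pw$mets)]
    var_stoich[[j]] <- stats::setNames(c(-1, 1), c(src, ext_mets[j]))
  }
  arch1 <- sample(c(TRUE, FALSE), n_variable_reactions, replace = TRUE)
  flip <- sample(n_variable_reactions, separation)
  arch2 <- arch1; arch2[flip] <- !arch2[flip]
  labels <- sample(rep(1:2, length.out = n_models))
  models <- vector("list", n_models)
  wt <- fba(base)$objective_value
  for (i in seq_len(n_models)) {
    pres <- if (labels[i] == 1) arch1 else arch2
    noise_flip <- stats::runif(n_variable_reactions) < noise
    pres <- xor(pres, noise_flip)
    mid <- sprintf("model_%03d", i)
    keep <- which(pres)
    m <- gem(id = mid,
             metabolites = rbind(base$mets,
                                 data.frame(id = ext_mets[keep],
                                            name = ext_mets[keep],
                                            compartment = "c",
                                            stringsAsFactors = FALSE)),
             reactions = rbind(base$rxns,
                               data.frame(id = var_ids[keep], lb = 0, ub = 1000,
                                          gpr = "", stringsAsFactors = FALSE)),
             stoichiometry = c(base$stoich, stats::setNames(var_stoich[keep], var_ids[keep])),
             objective = base$objective)
    attr(m, "pathways") <- pathways
    if (fba(m)$objective_value <= 0 || !isTRUE(all.equal(fba(m)$objective_value, wt)))
      stop("ensemble generation produced a model without positive growth")
    models[[i]] <- m
  }
  names(models) <- vapply(models, `[[`, character(1), "id")
  truth <- list(model_cluster_labels = stats::setNames(labels, names(models)),
                variable_reactions = var_ids,
                archetypes = list(arch1 = var_ids[arch1], arch2 = var_ids[arch2]),
                seed = seed)
  list(models = models, truth = truth)
}

#' Generate an expression matrix with planted DE and co-expression blocks
#'
#' Expression is log-normal: gene baselines are drawn on the log2 scale and
#' noise added there. Planted survival-associated genes shift by
#' \code{de_effect} (log2 units) in the low-survival tertile relative to the
#' rest: \code{n_de_up} genes are upregulated in low survival, \code{n_de_down}
#' downregulated. Co-expression blocks are generated from a shared latent
#' factor with loading \eqn{\sqrt{\rho}}, giving expected pairwise
#' correlation \code{block_rho} within each block. Survival times are drawn
#' from an exponential with the given median and all patients are recorded
#' with vital status "dead" (the cohort convention downstream stages keep).
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param surv_median_days Median of the exponential survival draw.
#' @param de_effect Log2 effect size for planted DE genes.
#' @param n_de_up,n_de_down Planted gene counts (up/down in low survival).
#' @param block_sizes Integer vector of co-expression block sizes.
#' @param block_rho Within-block expected pairwise correlation.
#' @param seed Integer seed.
#' @return List with \code{expression} (genes x samples, linear scale),
#'   \code{clinical} (sample_id, vital_status, days), and \code{truth}
#'   (fields \code{de_genes_up}, \code{de_genes_down}, \code{coexpr_blocks},
#'   \code{seed}).
#' @export
generate_expression <- function(n_genes, n_samples, surv_median_days = 350,
                                de_effect = 2, n_de_up = 0L, n_de_down = 0L,
                                block_sizes = integer(), block_rho = 0.99,
                                seed = 1L) {
  stopifnot(sum(block_sizes) <= n_genes)
  set.seed(seed)
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  samples <- sprintf("sample_%03d", seq_len(n_samples))
  days <- ceiling(stats::rexp(n_samples, rate = log(2) / surv_median_days))
  clinical <- data.frame(sample_id = samples, vital_status = "dead",
                         days = days, stringsAsFactors = FALSE)
  logx <- matrix(stats::rnorm(n_genes * n_samples, mean = 0, sd = 1),
                 n_genes, n_samples, dimnames = list(genes, samples))
  logx <- logx + stats::rnorm(n_genes, mean = 6, sd = 1.5)  # gene baselines

  blocks <- list()
  at <- 1L
  for (b in seq_along(block_sizes)) {
    sz <- block_sizes[b]
    idx <- at:(at + sz - 1L)
    f <- stats::rnorm(n_samples)
    logx[idx, ] <- sweep(sqrt(1 - block_rho) *
                           matrix(stats::rnorm(sz * n_samples), sz, n_samples),
                         2, sqrt(block_rho) * f, `+`) +
      stats::rnorm(sz, mean = 6, sd = 1.5)
    blocks[[b]] <- genes[idx]
    at <- at + sz
  }

  n_de <- n_de_up + n_de_down
  de_up <- de_down <- character()
  if (n_de > 0) {
    if (at + n_de - 1L > n_genes)
      stop("not enough genes outside co-expression blocks for planted DE genes")
    cuts <- stats::quantile(days, c(1/3, 2/3), type = 7)
    if (cuts[1] >= cuts[2])
      stop("degenerate survival distribution: tertile cut points coincide")
    low <- days < cuts[1]
    de_up <- genes[at:(at + n_de_up - 1L)][seq_len(n_de_up)]
    de_down <- genes[(at + n_de_up):(at + n_de - 1L)][seq_len(n_de_down)]
    logx[de_up, low] <- logx[de_up, low] + de_effect
    logx[de_down, low] <- logx[de_down, low] - de_effect
  }

  list(expression = 2^logx,
       clinical = clinical,
       truth = list(de_genes_up = de_up, de_genes_down = de_down,
                    coexpr_blocks = blocks, seed = seed))
}

#' Generate a metabolic task battery with known feasibility
#'
#' Feasible tasks ask for production of a metabolite downstream of an open
#' pathway input of the model; infeasible tasks demand an output whose every
#' producing route is excluded (the output lies on a different pathway than
#' the allowed input, and pathways are independent chains). Requires a model
#' carrying the pathway annotation from [generate_toy_gem()].
#'
#' @param model Annotated \code{gem}.
#' @param n_tasks Total number of tasks.
#' @param n_infeasible How many planted-infeasible tasks (needs >= 2 pathways).
#' @param seed Integer seed.
#' @return List with \code{tasks} (data frame in the task TSV layout: columns
#'   \code{task_id}, \code{description}, \code{direction}, \code{metabolite},
#'   \code{lower}, \code{upper}, \code{should_fail}) and \code{truth}
#'   (\code{feasible}: named logical per task).
#' @export
generate_tasks <- function(model, n_tasks, n_infeasible = 0L, seed = 1L) {
  stopifnot(n_infeasible <= n_tasks)
  pathways <- attr(model, "pathways")
  if (is.null(pathways))
    stop("model lacks pathway annotation; use generate_toy_gem()")
  if (n_infeasible > 0 && length(pathways) < 2)
    stop("planted-infeasible tasks need at least two pathways")
  set.seed(seed)
  rows <- list()
  feasible <- stats::setNames(logical(n_tasks), sprintf("task_%03d", seq_len(n_tasks)))
  for (t in seq_len(n_tasks)) {
    tid <- sprintf("task_%03d", t)
    infeas <- t > n_tasks - n_infeasible
    p <- sample(length(pathways), 1)
    q <- if (infeas) sample(setdiff(seq_along(pathways), p), 1) else p
    pw_in <- pathways[[p]]; pw_out <- pathways[[q]]
    out_met <- pw_out$mets[1 + sample(length(pw_out$mets) - 1L, 1)]
    rows[[length(rows) + 1L]] <- data.frame(
      task_id = tid,
      description = if (infeas) paste0("produce ", out_met, " from ", pw_in$name, " input (no route)")
                    else paste0("produce ", out_met, " from ", pw_in$name, " input"),
      direction = c("in", "out"),
      metabolite = c(pw_in$mets[1], out_met),
      lower = c(0, 0.05),
      upper = c(10, 10),
      should_fail = FALSE,
      stringsAsFactors = FALSE)
    feasible[tid] <- !infeas
  }
  list(tasks = do.call(rbind, rows), truth = list(feasible = feasible, seed = seed))
}

#' Generate a gene x cell-line dependency score matrix
#'
#' Emulates CRISPR-screen gene dependency scores: essential genes score
#' around -1 per cell line, non-essential genes around 0, with Gaussian
#' noise.
#'
#' @param genes Character vector of gene ids.
#' @param n_cell_lines Number of cell lines (columns).
#' @param essential_genes Subset of \code{genes} planted as essential.
#' @param sd Noise standard deviation.
#' @param seed Integer seed.
#' @return Numeric matrix (genes x cell lines).
#' @export
generate_dependency_matrix <- function(genes, n_cell_lines, essential_genes = character(),
                                       sd = 0.1, seed = 1L) {
  stopifnot(all(essential_genes %in% genes))
  set.seed(seed)
  mu <- ifelse(genes %in% essential_genes, -1, 0)
  matrix(stats::rnorm(length(genes) * n_cell_lines, mean = mu, sd = sd),
         nrow = length(genes),
         dimnames = list(genes, sprintf("cell_line_%02d", seq_len(n_cell_lines))))
}

#' Generate a paired tumor/healthy screening scenario
#'
#' Builds a tumor model and a healthy-tissue model sharing a subset of
#' pathways (same reaction and gene ids). Tumor-essential genes on shared
#' pathways break the healthy model's tasks when their reactions are removed
#' (planted toxic); tumor-essential genes on tumor-private pathways are
#' absent from the healthy model (planted nontoxic). The healthy task
#' battery asks for the terminal product of each healthy pathway.
#'
#' @param n_shared Number of pathways present in both models.
#' @param n_tumor_private Pathways only in the tumor model.
#' @param n_healthy_private Pathways only in the healthy model.
#' @param gpr_mix Rule-type proportions, as in [generate_toy_gem()].
#' @param seed Integer seed.
#' @return List with \code{tumor}, \code{healthy} (both \code{gem}),
#'   \code{tasks} (healthy task battery data frame), and \code{truth}
#'   (fields \code{essential_genes}, \code{toxic_genes},
#'   \code{nontoxic_essential}, \code{seed}).
#' @export
generate_screen_scenario <- function(n_shared = 2L, n_tumor_private = 2L,
                                     n_healthy_private = 1L,
                                     gpr_mix = c(single = 0.5, or = 0.25, and = 0.25),
                                     seed = 1L) {
  stopifnot(n_shared >= 1, n_tumor_private >= 1)
  gpr_mix <- gpr_mix / sum(gpr_mix)
  set.seed(seed)
  mk <- function(name) {
    len <- sample(2:4, 1)
    types <- sample(names(gpr_mix), len, replace = TRUE, prob = gpr_mix)
    make_pathway_spec(name, len, types)
  }
  shared <- lapply(paste0("SH", seq_len(n_shared)), mk)
  tumor_priv <- lapply(paste0("TP", seq_len(n_tumor_private)), mk)
  healthy_priv <- if (n_healthy_private > 0)
    lapply(paste0("HP", seq_len(n_healthy_private)), mk) else list()

  tumor <- build_pathway_model("tumor", c(shared, tumor_priv))
  healthy <- build_pathway_model("healthy", c(shared, healthy_priv))

  ess <- function(specs) sort(unlist(lapply(specs, `[[`, "genes_essential")))
  essential <- c(ess(shared), ess(tumor_priv))
  toxic <- ess(shared)
  nontoxic <- ess(tumor_priv)

  hp <- attr(healthy, "pathways")
  rows <- lapply(seq_along(hp), function(i) {
    pw <- hp[[i]]
    data.frame(task_id = sprintf("task_%03d", i),
               description = paste0("synthesize ", pw$mets[length(pw$mets)]),
               direction = c("in", "out"),
               metabolite = c(pw$mets[1], pw$mets[length(pw$mets)]),
               lower = c(0, 0.05), upper = c(10, 10),
               should_fail = FALSE, stringsAsFactors = FALSE)
  })
  list(tumor = tumor, healthy = healthy, tasks = do.call(rbind, rows),
       truth = list(essential_genes = sort(essential),
                    toxic_genes = sort(toxic),
                    nontoxic_essential = sort(nontoxic),
                    seed = seed))
}

#' Write a planted-truth record as JSON
#'
#' @param truth A truth list from any generator.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
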