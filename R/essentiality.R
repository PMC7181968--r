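#' Logic transformation of a model (LTM)
#'
#' Rewrites a model so that every reaction carries exactly one gene label,
#' which makes single-gene knockout scans a matter of zeroing reaction bounds
#' rather than re-evaluating boolean rules. Each GPR is converted to
#' disjunctive normal form; a reaction with \eqn{d} disjuncts is expanded
#' into \eqn{d} parallel duplicates, one per disjunct. A disjunct of one gene
#' keeps that gene as its label; an AND-conjunction gets a composite
#' pseudo-gene label whose knockout is triggered by any constituent.
#'
#' Pure duplication would multiply pathway capacity, so the duplicates share
#' the source reaction's bounds through a capacity-coupling pseudo-metabolite:
#' every duplicate co-produces one unit of the coupling metabolite per unit
#' flux, and a single spontaneous drain reaction carrying the original bounds
#' consumes it. The summed duplicate flux therefore stays inside the original
#' bounds and the wild-type optimum is preserved exactly.
#'
#' Rules whose DNF exceeds \code{max_disjuncts} are left unexpanded and
#' flagged; knockout routines fall back to direct rule evaluation for them.
#'
#' @param model A \code{gem} object.
#' @param max_disjuncts Cap on DNF expansion per reaction.
#' @return An object of class \code{c("ltm_gem", "gem")} with extra fields:
#'   \code{pseudo_genes} (named list mapping composite labels to constituent
#'   genes), \code{rxn_map} (named character, expanded reaction -> source
#'   reaction), and \code{fallback} (ids of unexpanded reactions).
#' @export
logic_transform <- function(model, max_disjuncts = 64L) {
  validate_gem(model)
  mets <- model$mets
  rx_id <- character(); rx_lb <- numeric(); rx_ub <- numeric(); rx_gpr <- character()
  stoich <- list()
  pseudo <- list()
  rxn_map <- character()
  fallback <- character()

  label_for <- function(conj) {
    if (length(conj) == 1L) return(conj)
    lab <- paste(conj, collapse = "__AND__")
    pseudo[[lab]] <<- conj
    lab
  }
  add_rxn <- function(id, lb, ub, gpr, s, src) {
    rx_id[length(rx_id) + 1L] <<- id
    rx_lb[length(rx_lb) + 1L] <<- lb
    rx_ub[length(rx_ub) + 1L] <<- ub
    rx_gpr[length(rx_gpr) + 1L] <<- gpr
    stoich[[id]] <<- s
    rxn_map[id] <<- src
  }

  for (i in seq_len(nrow(model$rxns))) {
    rid <- model$rxns$id[i]
    lb <- model$rxns$lb[i]; ub <- model$rxns$ub[i]
    s <- model$stoich[[rid]]
    dnf <- gpr_to_dnf(model$gprs[[i]], max_disjuncts = max_disjuncts)
    if (is.null(dnf)) {
      warning("GPR of reaction '", rid, "' exceeds ", max_disjuncts,
              " disjuncts; using direct rule evaluation for it")
      fallback <- c(fallback, rid)
      add_rxn(rid, lb, ub, model$rxns$gpr[i], s, rid)
    } else if (length(dnf) <= 1L) {
      gpr <- if (length(dnf)) label_for(dnf[[1]]) else ""
      add_rxn(rid, lb, ub, gpr, s, rid)
    } else {
      cap_met <- paste0("ltmcap__", rid)
      mets <- rbind(mets, data.frame(id = cap_met, name = cap_met,
                                     compartment = "ltm",
                                     stringsAsFactors = FALSE))
      for (d in seq_along(dnf)) {
        dup <- paste0(rid, "__dnf", d)
        add_rxn(dup, min(lb, 0), max(ub, 0), label_for(dnf[[d]]),
                c(s, stats::setNames(1, cap_met)), rid)
      }
      drain <- paste0("ltmdrain__", rid)
      add_rxn(drain, lb, ub, "", stats::setNames(-1, cap_met), rid)
    }
  }

  objective <- model$objective
  if (!objective %in% rx_id) {
    # objective was OR-expanded: its drain carries the combined flux
    objective <- paste0("ltmdrain__", model$objective)
  }
  out <- gem(id = paste0(model$id, "_ltm"),
             metabolites = mets,
             reactions = data.frame(id = rx_id, lb = rx_lb, ub = rx_ub,
                                    gpr = rx_gpr, stringsAsFactors = FALSE),
             stoichiometry = stoich,
             objective = objective)
  out$pseudo_genes <- pseudo
  out$rxn_map <- rxn_map
  out$fallback <- fallback
  out$source_genes <- model_genes(model)
  class(out) <- c("ltm_gem", "gem")
  out
}

#' Reactions of an LTM model disabled by a gene knockout
#'
#' @param ltm An \code{ltm_gem}.
#' @param gene A single original gene id.
#' @return Character vector of expanded-reaction ids to zero out.
#' @keywords internal
ltm_disabled_reactions <- function(ltm, gene) {
  labels <- ltm$rxns$gpr
  hit <- labels == gene
  if (length(ltm$pseudo_genes)) {
    composite <- names(ltm$pseudo_genes)[vapply(ltm$pseudo_genes,
                                                function(g) gene %in% g, logical(1))]
    hit <- hit | labels %in% composite
  }
  direct <- ltm$rxns$id %in% ltm$fallback &
    !vapply(ltm$gprs, evaluate_gpr, logical(1), knocked_out = gene)
  ltm$rxns$id[hit | direct]
}

#' Single-gene essentiality scan
#'
#' Knocks out every gene of the model in turn and maximizes biomass. A gene
#' is essential when its knockout growth falls below
#' \code{threshold * wild-type growth} — the knockout makes the cell fail its
#' growth objective. Two equivalent routes are available: \code{"ltm"}
#' (default) performs one [logic_transform()] and then zeroes per-label
#' reaction bounds for each gene; \code{"direct"} re-evaluates all GPRs per
#' gene via [apply_knockout()]. Both give identical growth values.
#'
#' @param model A \code{gem} object.
#' @param threshold Growth-ratio cutoff below which a gene is essential.
#' @param method \code{"ltm"} or \code{"direct"}.
#' @return An \code{essentiality_result}: data frame with columns
#'   \code{gene}, \code{ko_growth}, \code{growth_ratio}, \code{essential},
#'   plus attributes \code{wild_type_growth} and \code{threshold}.
#' @export
essential_genes <- function(model, threshold = 1e-3, method = c("ltm", "direct")) {
  method <- match.arg(method)
  wt <- fba(model)
  if (wt$status != "optimal")
    stop("wild-type FBA is ", wt$status, "; essentiality undefined")
  if (wt$objective_value <= 0)
    stop("wild-type growth is zero; essentiality undefined")
  genes <- model_genes(model)
  work <- if (method == "ltm") logic_transform(model) else model
  ko_growth <- vapply(genes, function(g) {
    m2 <- if (method == "ltm") {
      set_bounds(work, ltm_disabled_reactions(work, g), 0, 0)
    } else {
      apply_knockout(work, g)
    }
    sol <- fba(m2)
    if (sol$status == "optimal") sol$objective_value else 0
  }, numeric(1))
  ratio <- pmin(pmax(ko_growth / wt$objective_value, 0), 1 + 1e-6)
  out <- data.frame(gene = genes,
                    ko_growth = unname(ko_growth),
                    growth_ratio = unname(ratio),
                    essential = unname(ratio < threshold),
                    stringsAsFactors = FALSE)
  attr(out, "wild_type_growth") <- wt$objective_value
  attr(out, "threshold") <- threshold
  class(out) <- c("essentiality_result", "data.frame")
  out
}

#' Consensus essentiality across a model ensemble
#'
#' Runs [essential_genes()] on every member model and tallies, per gene, the
#' fraction of models in which it is essential. Genes absent from a model are
#' counted as non-essential there (the number of models actually carrying
#' the gene is reported separately, and a presence-restricted fraction
#' alongside). The consensus set contains genes essential in all models; the
#' union set contains genes essential in at least one.
#'
#' @param models List of \code{gem} objects (distinct ids).
#' @param threshold Growth-ratio cutoff passed to [essential_genes()].
#' @param method Knockout route passed to [essential_genes()].
#' @return List with \code{per_gene} (data frame: \code{gene},
#'   \code{n_essential}, \code{n_present}, \code{fraction} over all models,
#'   \code{fraction_present} over models carrying the gene),
#'   \code{consensus} (genes with fraction 1), \code{union} (genes essential
#'   somewhere), and \code{n_models}.
#' @export
consensus_essentiality <- function(models, threshold = 1e-3,
                                   method = c("ltm", "direct")) {
  method <- match.arg(method)
  stopifnot(length(models) >= 1L)
  ids <- vapply(models, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate model ids in ensemble")
  results <- lapply(models, essential_genes, threshold = threshold, method = method)
  genes <- sort(unique(unlist(lapply(results, `[[`, "gene"))))
  n_ess <- n_pres <- stats::setNames(integer(length(genes)), genes)
  for (res in results) {
    n_pres[res$gene] <- n_pres[res$gene] + 1L
    ess <- res$gene[res$essential]
    n_ess[ess] <- n_ess[ess] + 1L
  }
  per_gene <- data.frame(gene = genes,
                         n_essential = unname(n_ess),
                         n_present = unname(n_pres),
                         fraction = unname(n_ess) / length(models),
                         fraction_present = ifelse(n_pres > 0, n_ess / n_pres, NA_real_),
                         stringsAsFactors = FALSE)
  list(per_gene = per_gene,
       consensus = genes[per_gene$fraction == 1],
       union = genes[per_gene$n_essential > 0],
       n_models = length(models))
}

#' Write an essentiality result to TSV
#'
#' @param result An \code{essentiality_result}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_essentiality <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
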