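#' Metabolic task batteries
#'
#' A metabolic task asks whether a model can produce specified outputs from
#' specified allowed inputs — protein synthesis from amino acids, nucleotide
#' synthesis from precursors, and the like. Tasks are carried as a flat data
#' frame, one row per constrained metabolite, with columns \code{task_id},
#' \code{description}, \code{direction} (\code{"in"}/\code{"out"}),
#' \code{metabolite}, \code{lower}, \code{upper}, \code{should_fail}. This is
#' an importable flattening of the spreadsheet layouts task collections are
#' published in; fields beyond these are not interpreted.
#'
#' @name metabolic_tasks
NULL

#' @rdname metabolic_tasks
#' @param path Task TSV path.
#' @return \code{read_tasks}: the task data frame, validated.
#' @export
read_tasks <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  validate_tasks(df)
}

#' @rdname metabolic_tasks
#' @param tasks Task data frame.
#' @export
write_tasks <- function(tasks, path) {
  utils::write.table(validate_tasks(tasks), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_tasks <- function(tasks) {
  need <- c("task_id", "direction", "metabolite", "lower", "upper")
  miss <- setdiff(need, names(tasks))
  if (length(miss))
    stop("task table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(tasks$description)) tasks$description <- ""
  if (is.null(tasks$should_fail)) tasks$should_fail <- FALSE
  if (!all(tasks$direction %in% c("in", "out")))
    stop("task direction must be 'in' or 'out'")
  if (any(tasks$lower < 0 | tasks$upper < tasks$lower))
    stop("task bounds must satisfy 0 <= lower <= upper")
  tasks
}

#' Check whether a model can perform a metabolic task
#'
#' Builds the task LP: all boundary exchange reactions are closed, then for
#' each task input an uptake reaction bounded by the task's uptake interval
#' is opened, and for each task output a sink reaction is added whose flux is
#' forced into the production interval. The task passes iff the resulting
#' steady-state system is feasible; a task marked \code{should_fail} passes
#' iff the system is infeasible. Tasks naming metabolites absent from the
#' model are untestable and reported as such, never as passes.
#'
#' @param model A \code{gem} object.
#' @param task Rows of a task data frame for one \code{task_id}.
#' @return List with \code{task_id}, \code{status} (\code{"pass"},
#'   \code{"fail"}, or \code{"untestable"}), and \code{feasible} (the raw LP
#'   feasibility, NA if untestable).
#' @export
check_task <- function(model, task) {
  task <- validate_tasks(task)
  tid <- unique(task$task_id)
  stopifnot(length(tid) == 1)
  unresolved <- setdiff(task$metabolite, model$mets$id)
  if (length(unresolved))
    return(list(task_id = tid, status = "untestable", feasible = NA,
                unresolved = unresolved))
  work <- set_bounds(model, exchange_reactions(model), 0, 0)
  # objective may not force flux during a feasibility probe
  work$rxns$lb[work$rxns$id == work$objective] <- min(0, work$rxns$lb[work$rxns$id == work$objective])
  S <- stoichiometric_matrix(work)
  lb <- work$rxns$lb; ub <- work$rxns$ub
  ins <- task[task$direction == "in", , drop = FALSE]
  outs <- task[task$direction == "out", , drop = FALSE]
  addcols <- function(mets, sign) {
    M <- matrix(0, nrow(S), nrow(mets))
    rownames(M) <- rownames(S)
    for (i in seq_len(nrow(mets))) M[mets$metabolite[i], i] <- sign
    M
  }
  A <- cbind(S, addcols(ins, 1), addcols(outs, -1))
  lb <- c(lb, ins$lower, outs$lower)
  ub <- c(ub, ins$upper, outs$upper)
  feasible <- lp_feasible(A, rep(0, nrow(A)), lb, ub)
  sf <- isTRUE(task$should_fail[1])
  pass <- if (sf) !feasible else feasible
  list(task_id = tid, status = if (pass) "pass" else "fail", feasible = feasible)
}

#' Run a full task battery against a model
#'
#' @param model A \code{gem} object.
#' @param tasks Task data frame (possibly many task ids).
#' @return Data frame with columns \code{task_id}, \code{status},
#'   \code{feasible}.
#' @export
check_tasks <- function(model, tasks) {
  tasks <- validate_tasks(tasks)
  ids <- unique(tasks$task_id)
  rows <- lapply(ids, function(tid) {
    res <- check_task(model, tasks[tasks$task_id == tid, , drop = FALSE])
    data.frame(task_id = tid, status = res$status,
               feasible = if (is.na(res$feasible)) NA else res$feasible,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reactions coupled to a gene
#'
#' Default mode (\code{"knockout"}) returns the reactions disabled by
#' knocking out the gene — those whose GPR evaluates false without it, the
#' same coupling the tumor-side knockout uses. Mode \code{"listing"} returns
#' every reaction merely mentioning the gene in its rule (an isozyme-covered
#' reaction is listed but not knockout-coupled).
#'
#' @param model A \code{gem} object.
#' @param gene A gene id known to the model.
#' @param mode \code{"knockout"} or \code{"listing"}.
#' @return Character vector of reaction ids.
#' @export
gene_reactions <- function(model, gene, mode = c("knockout", "listing")) {
  mode <- match.arg(mode)
  if (!gene %in% model_genes(model))
    stop("gene '", gene, "' not in model '", model$id, "'")
  if (mode == "listing") {
    hit <- vapply(model$gprs, function(a) gene %in% gpr_genes(a), logical(1))
  } else {
    hit <- !vapply(model$gprs, evaluate_gpr, logical(1), knocked_out = gene)
  }
  model$rxns$id[hit]
}

#' Toxicity screen of candidate genes on a healthy-tissue model
#'
#' For each candidate gene independently, removes its coupled reactions from
#' the intact healthy model, runs the full task battery, and restores the
#' model. A candidate is toxic when any task's verdict turns to fail.
#' Before screening, the unmodified healthy model must pass its entire
#' battery — a baseline failure indicates a model/task mismatch and aborts
#' the screen. Candidates absent from the healthy model cannot perturb it
#' and are nontoxic by definition (flagged \code{absent}).
#'
#' @param healthy A \code{gem} of the healthy tissue.
#' @param tasks Task data frame.
#' @param candidates Gene ids to screen (typically tumor-essential genes).
#' @param coupling Reaction-coupling mode, see [gene_reactions()].
#' @return A \code{toxicity_report}: list with \code{summary} (data frame:
#'   \code{gene}, \code{absent}, \code{n_reactions_removed},
#'   \code{n_tasks_failed}, \code{toxic}), \code{task_status} (tasks x genes
#'   status matrix), \code{untestable} (task ids), and \code{baseline}.
#' @export
toxicity_screen <- function(healthy, tasks, candidates,
                            coupling = c("knockout", "listing")) {
  coupling <- match.arg(coupling)
  tasks <- validate_tasks(tasks)
  baseline <- check_tasks(healthy, tasks)
  untestable <- baseline$task_id[baseline$status == "untestable"]
  testable <- baseline[baseline$status != "untestable", , drop = FALSE]
  if (any(testable$status == "fail"))
    stop("baseline model fails task(s) ",
         paste(testable$task_id[testable$status == "fail"], collapse = ", "),
         "; screen aborted (model-quality error)")
  genes <- model_genes(healthy)
  n <- length(candidates)
  status <- matrix(NA_character_, nrow(testable), n,
                   dimnames = list(testable$task_id, candidates))
  summary <- data.frame(gene = candidates, absent = !(candidates %in% genes),
                        n_reactions_removed = 0L, n_tasks_failed = 0L,
                        toxic = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    g <- candidates[i]
    if (summary$absent[i]) {
      status[, i] <- "pass"
      next
    }
    rxns <- gene_reactions(healthy, g, mode = coupling)
    rxns <- setdiff(rxns, healthy$objective)
    summary$n_reactions_removed[i] <- length(rxns)
    pert <- if (length(rxns)) set_bounds(healthy, rxns, 0, 0) else healthy
    res <- check_tasks(pert, tasks)
    res <- res[match(testable$task_id, res$task_id), , drop = FALSE]
    status[, i] <- res$status
    summary$n_tasks_failed[i] <- sum(res$status == "fail")
    summary$toxic[i] <- summary$n_tasks_failed[i] > 0
  }
  structure(list(summary = summary, task_status = status,
                 untestable = untestable, baseline = baseline,
                 coupling = coupling),
            class = "toxicity_report")
}

#' @export
print.toxicity_report <- function(x, ...) {
  cat("Toxicity screen of", nrow(x$summary), "candidate gene(s) over",
      nrow(x$task_status), "testable task(s)\n")
  cat("  toxic:", sum(x$summary$toxic),
      " nontoxic:", sum(!x$summary$toxic),
      " (absent from healthy model:", sum(x$summary$absent), ")\n")
  invisible(x)
}

#' Shortlist nontoxic essential genes as drug-target candidates
#'
#' Intersects tumor essentiality with the healthy-tissue toxicity screen:
#' keep genes that are essential in the tumor model and nontoxic in the
#' healthy model, sorted by knockout growth ratio ascending (strongest
#' growth effect first).
#'
#' @param essentiality An \code{essentiality_result} for the tumor model.
#' @param report A \code{toxicity_report} screened over the essential genes.
#' @return Character vector of shortlisted gene ids.
#' @export
shortlist_targets <- function(essentiality, report) {
  ess <- essentiality$gene[essentiality$essential]
  screened <- report$summary$gene
  if (length(ess) && !length(intersect(ess, screened)))
    stop("screen/essentiality mismatch: no essential gene was screened")
  nontoxic <- report$summary$gene[!report$summary$toxic]
  keep <- intersect(ess, nontoxic)
  ratios <- essentiality$growth_ratio[match(keep, essentiality$gene)]
  keep[order(ratios, keep)]
}

#' Write a toxicity report
#'
#' TSV summary (gene, tasks failed, toxic flag) plus a JSON with the
#' per-task status detail.
#'
#' @param report A \code{toxicity_report}.
#' @param path Output TSV path; the JSON detail lands next to it with
#'   extension \code{.json}.
#' @return The path, invisibly.
#' @export
write_toxicity_report <- function(report, path) {
  utils::write.table(report$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  detail <- list(coupling = report$coupling,
                 untestable = report$untestable,
                 task_status = as.data.frame(report$task_status))
  jsonlite::write_json(detail, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
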