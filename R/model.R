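#' Construct a genome-scale metabolic model
#'
#' A \code{gem} object bundles the ingredients of constraint-based modeling:
#' metabolites, reactions with stoichiometry and flux bounds, boolean GPR
#' rules, and a biomass (objective) reaction whose maximal flux proxies
#' growth. Steady-state mass balance applies to every metabolite; exchange
#' with the environment is modeled by explicit single-metabolite boundary
#' reactions, never by exempting metabolites from the balance.
#'
#' @param id Model identifier.
#' @param metabolites Data frame with columns \code{id}, \code{name},
#'   \code{compartment} (\code{name} optional, defaults to \code{id};
#'   \code{compartment} defaults to \code{"c"}).
#' @param reactions Data frame with columns \code{id}, \code{lb}, \code{ub},
#'   \code{gpr} (rule string, \code{""} for spontaneous). Missing bounds take
#'   the conventional defaults: irreversible \code{(0, 1000)}; callers wanting
#'   reversibility must supply a negative \code{lb}.
#' @param stoichiometry Named list, one entry per reaction id, each a named
#'   numeric vector of metabolite coefficients (negative = consumed).
#' @param objective Reaction id of the biomass/objective reaction.
#' @return An object of class \code{gem}.
#' @export
#' @examples
#' m <- gem(
#'   id = "chain",
#'   metabolites = data.frame(id = "A", compartment = "c"),
#'   reactions = data.frame(id = c("EX_A", "BIOMASS"),
#'                          lb = c(0, 0), ub = c(10, 5), gpr = c("", "g1")),
#'   stoichiometry = list(EX_A = c(A = 1), BIOMASS = c(A = -1)),
#'   objective = "BIOMASS")
#' fba(m)$objective_value
gem <- function(id, metabolites, reactions, stoichiometry, objective) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  metabolites$name[is.na(metabolites$name)] <- metabolites$id[is.na(metabolites$name)]
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(reactions$lb)) reactions$lb <- 0
  if (is.null(reactions$ub)) reactions$ub <- 1000
  reactions$lb[is.na(reactions$lb)] <- 0
  reactions$ub[is.na(reactions$ub)] <- 1000
  metabolites <- metabolites[, c("id", "name", "compartment")]
  reactions <- reactions[, c("id", "lb", "ub", "gpr")]
  rownames(metabolites) <- NULL
  rownames(reactions) <- NULL
  gprs <- lapply(reactions$gpr, parse_gpr)
  m <- structure(
    list(id = id,
         mets = metabolites,
         rxns = reactions,
         stoich = stoichiometry[reactions$id],
         gprs = gprs,
         objective = objective),
    class = "gem")
  validate_gem(m)
  m
}

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, non-empty compartments, bound ordering, non-empty
#' stoichiometries whose metabolites all resolve, and that the objective
#' reaction exists. Called by the constructor and after structural edits.
#'
#' @param model A \code{gem} object.
#' @return The model, invisibly; stops with an informative error otherwise.
#' @export
validate_gem <- function(model) {
  stopifnot(inherits(model, "gem"))
  if (anyDuplicated(model$mets$id))
    stop("duplicate metabolite ids: ",
         paste(unique(model$mets$id[duplicated(model$mets$id)]), collapse = ", "))
  if (anyDuplicated(model$rxns$id))
    stop("duplicate reaction ids: ",
         paste(unique(model$rxns$id[duplicated(model$rxns$id)]), collapse = ", "))
  if (any(!nzchar(model$mets$compartment)))
    stop("empty compartment tag for metabolite(s): ",
         paste(model$mets$id[!nzchar(model$mets$compartment)], collapse = ", "))
  bad <- model$rxns$lb > model$rxns$ub
  if (any(bad))
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(model$rxns$id[bad], collapse = ", "))
  if (length(model$stoich) != nrow(model$rxns) ||
      !identical(names(model$stoich), model$rxns$id))
    stop("stoichiometry list must have exactly one entry per reaction id")
  for (rid in model$rxns$id) {
    s <- model$stoich[[rid]]
    if (length(s) == 0L)
      stop("reaction '", rid, "' has empty stoichiometry")
    unknown <- setdiff(names(s), model$mets$id)
    if (length(unknown))
      stop("reaction '", rid, "' references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
  }
  if (!model$objective %in% model$rxns$id)
    stop("objective reaction '", model$objective, "' not found in model")
  invisible(model)
}

#' Genes of a model
#'
#' The gene set is derived as the union of all GPR leaves.
#'
#' @param model A \code{gem} object.
#' @return Sorted character vector of gene ids.
#' @export
model_genes <- function(model) {
  sort(unique(unlist(lapply(model$gprs, gpr_genes))))
}

#' Reaction ids of a model
#' @param model A \code{gem} object.
#' @return Character vector of reaction ids in model order.
#' @export
model_reactions <- function(model) model$rxns$id

#' Identify boundary exchange reactions
#'
#' Exchange reactions connect the network to the environment and are
#' recognized by their single-metabolite stoichiometry.
#'
#' @param model A \code{gem} object.
#' @return Character vector of exchange reaction ids.
#' @export
exchange_reactions <- function(model) {
  model$rxns$id[vapply(model$stoich, length, integer(1)) == 1L]
}

#' Build the stoichiometric matrix
#'
#' @param model A \code{gem} object.
#' @return Dense numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  S <- matrix(0, nrow(model$mets), nrow(model$rxns),
              dimnames = list(model$mets$id, model$rxns$id))
  for (j in seq_along(model$stoich)) {
    s <- model$stoich[[j]]
    S[names(s), j] <- s
  }
  S
}

#' Apply a gene knockout to a model
#'
#' Every reaction whose GPR evaluates to \code{FALSE} under the knockout has
#' both flux bounds set to zero; spontaneous reactions and reactions still
#' covered by an isozyme are untouched. Gene ids not present in the model are
#' ignored with a warning.
#'
#' @param model A \code{gem} object.
#' @param knocked_out Character vector of gene ids to disable.
#' @return A modified copy of the model.
#' @export
apply_knockout <- function(model, knocked_out) {
  stopifnot(inherits(model, "gem"))
  knocked_out <- unique(as.character(knocked_out))
  unknown <- setdiff(knocked_out, model_genes(model))
  if (length(unknown))
    warning("ignoring gene id(s) absent from model '", model$id, "': ",
            paste(unknown, collapse = ", "))
  dead <- !vapply(model$gprs, evaluate_gpr, logical(1), knocked_out = knocked_out)
  model$rxns$lb[dead] <- 0
  model$rxns$ub[dead] <- 0
  model
}

#' Set flux bounds for selected reactions
#'
#' @param model A \code{gem} object.
#' @param reaction_ids Reaction ids to modify.
#' @param lb,ub New lower/upper bounds (recycled).
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction_ids, lb, ub) {
  idx <- match(reaction_ids, model$rxns$id)
  if (anyNA(idx))
    stop("unknown reaction id(s): ",
         paste(reaction_ids[is.na(idx)], collapse = ", "))
  model$rxns$lb[idx] <- rep_len(lb, length(idx))
  model$rxns$ub[idx] <- rep_len(ub, length(idx))
  model
}

#' Remove reactions from a model
#'
#' Metabolites left without any reaction are retained (they simply become
#' disconnected); downstream LPs pin their balance at zero trivially.
#'
#' @param model A \code{gem} object.
#' @param reaction_ids Reaction ids to drop; dropping the objective is an error.
#' @return The modified model.
#' @export
remove_reactions <- function(model, reaction_ids) {
  if (model$objective %in% reaction_ids)
    stop("cannot remove the objective reaction '", model$objective, "'")
  keep <- !model$rxns$id %in% reaction_ids
  model$rxns <- model$rxns[keep, , drop = FALSE]
  rownames(model$rxns) <- NULL
  model$stoich <- model$stoich[model$rxns$id]
  model$gprs <- model$gprs[keep]
  model
}

#' @export
print.gem <- function(x, ...) {
  cat("Genome-scale metabolic model '", x$id, "'\n", sep = "")
  cat("  metabolites:", nrow(x$mets),
      " reactions:", nrow(x$rxns),
      " genes:", length(model_genes(x)), "\n")
  cat("  objective:", x$objective, "\n")
  invisible(x)
}
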