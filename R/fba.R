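#' Flux balance analysis
#'
#' Maximizes the flux of the model's objective (biomass) reaction subject to
#' steady-state mass balance on every metabolite (\eqn{S v = 0}) and the
#' reaction flux bounds. Optimal solutions are checked on return: the
#' steady-state residual (max absolute net production over metabolites) must
#' be below \code{1e-6} and every flux within its bounds to \code{1e-9}.
#'
#' @param model A \code{gem} object.
#' @return A \code{flux_solution}: list with \code{status} (\code{"optimal"},
#'   \code{"infeasible"} or \code{"unbounded"}), \code{objective_value}, and
#'   \code{fluxes} (named vector over reactions; \code{NULL} unless optimal).
#' @export
#' @examples
#' m <- gem("chain",
#'          metabolites = data.frame(id = "A", compartment = "c"),
#'          reactions = data.frame(id = c("EX_A", "GROWTH"),
#'                                 lb = 0, ub = c(10, 5), gpr = ""),
#'          stoichiometry = list(EX_A = c(A = 1), GROWTH = c(A = -1)),
#'          objective = "GROWTH")
#' fba(m)
fba <- function(model) {
  validate_gem(model)
  S <- stoichiometric_matrix(model)
  obj <- as.numeric(model$rxns$id == model$objective)
  res <- lp_solve(obj, S, rep(0, nrow(S)), model$rxns$lb, model$rxns$ub,
                  maximize = TRUE)
  if (res$status != "optimal") {
    return(structure(list(status = res$status,
                          objective_value = if (res$status == "unbounded") Inf else NA_real_,
                          fluxes = NULL),
                     class = "flux_solution"))
  }
  v <- res$x
  names(v) <- model$rxns$id
  residual <- max(abs(S %*% v))
  if (residual > 1e-6)
    stop("FBA solution violates steady state (residual ", format(residual), ")")
  if (any(v < model$rxns$lb - 1e-9) || any(v > model$rxns$ub + 1e-9))
    stop("FBA solution violates flux bounds")
  structure(list(status = "optimal",
                 objective_value = unname(v[model$objective]),
                 fluxes = v),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("Flux solution:", x$status)
  if (x$status == "optimal")
    cat(", objective =", format(x$objective_value, digits = 8))
  cat("\n")
  invisible(x)
}

#' Write a flux solution to TSV
#'
#' Two columns: reaction id and flux value.
#'
#' @param solution A \code{flux_solution} with status \code{"optimal"}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_fluxes <- function(solution, path) {
  stopifnot(inherits(solution, "flux_solution"))
  if (solution$status != "optimal")
    stop("cannot export a non-optimal flux solution (status: ", solution$status, ")")
  utils::write.table(
    data.frame(reaction = names(solution$fluxes), flux = unname(solution$fluxes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
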