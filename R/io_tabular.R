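#' Read / write metabolic models in the sectioned tabular dialect
#'
#' A human-writable TSV dialect for small models and fixtures. The file has a
#' \code{[metabolites]} section (columns \code{id}, \code{name},
#' \code{compartment}) and a \code{[reactions]} section (columns \code{id},
#' \code{equation}, \code{lb}, \code{ub}, \code{gpr}, \code{objective}).
#' Equations use \code{"2 A + B => C"} with \code{"<=>"} for reversible
#' reactions; either side may be empty for boundary exchanges. Blank bounds
#' default to \code{(0, 1000)} for irreversible and \code{(-1000, 1000)} for
#' reversible reactions. Exactly one reaction must carry objective flag 1.
#'
#' @param path File path.
#' @return For \code{read_gem_tabular}, a \code{gem}; for the writer, the
#'   path invisibly.
#' @name tabular_io
NULL

#' @rdname tabular_io
#' @export
read_gem_tabular <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  model_id <- tools::file_path_sans_ext(basename(path))
  hdr <- grep("^#\\s*model:", lines, value = TRUE)
  if (length(hdr)) model_id <- trimws(sub("^#\\s*model:", "", hdr[1]))
  lines_clean <- ifelse(grepl("^#", lines), "", lines)

  sec_start <- grep("^\\[(metabolites|reactions)\\]\\s*$", lines_clean)
  if (!length(sec_start)) stop("parse error in ", path, ": no section headers found")
  sec_name <- sub("^\\[(\\w+)\\].*$", "\\1", lines_clean[sec_start])
  sec_end <- c(sec_start[-1] - 1L, length(lines_clean))

  section <- function(name) {
    k <- which(sec_name == name)
    if (!length(k)) stop("parse error in ", path, ": missing [", name, "] section")
    body <- lines_clean[(sec_start[k] + 1L):sec_end[k]]
    body <- body[nzchar(trimws(body))]
    if (!length(body)) stop("parse error in ", path, ": empty [", name, "] section")
    utils::read.table(text = paste(body, collapse = "\n"), sep = "\t",
                      header = TRUE, quote = "", comment.char = "",
                      colClasses = "character", check.names = FALSE)
  }

  mets <- section("metabolites")
  rx <- section("reactions")
  need <- setdiff(c("id", "equation"), names(rx))
  if (length(need))
    stop("parse error in ", path, ": [reactions] lacks column(s) ",
         paste(need, collapse = ", "))

  stoich <- vector("list", nrow(rx))
  lb <- ub <- numeric(nrow(rx))
  for (i in seq_len(nrow(rx))) {
    eq <- parse_reaction_equation(rx$equation[i], rx$id[i])
    stoich[[i]] <- eq$stoich
    unknown <- setdiff(names(eq$stoich), mets$id)
    if (length(unknown))
      stop("parse error in ", path, ": reaction '", rx$id[i],
           "' references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
    deflb <- if (eq$reversible) -1000 else 0
    lb[i] <- parse_bound(rx$lb[i], deflb)
    ub[i] <- parse_bound(rx$ub[i], 1000)
  }
  names(stoich) <- rx$id
  objflag <- if ("objective" %in% names(rx)) rx$objective else rep("0", nrow(rx))
  obj_idx <- which(trimws(objflag) %in% c("1", "true", "TRUE"))
  if (length(obj_idx) != 1L)
    stop("configuration error in ", path, ": exactly one reaction must be ",
         "flagged as objective (found ", length(obj_idx), ")")
  gpr <- if ("gpr" %in% names(rx)) rx$gpr else rep("", nrow(rx))
  gem(id = model_id,
      metabolites = data.frame(id = mets$id,
                               name = if ("name" %in% names(mets)) mets$name else mets$id,
                               compartment = if ("compartment" %in% names(mets)) mets$compartment else "c",
                               stringsAsFactors = FALSE),
      reactions = data.frame(id = rx$id, lb = lb, ub = ub, gpr = gpr,
                             stringsAsFactors = FALSE),
      stoichiometry = stoich,
      objective = rx$id[obj_idx])
}

parse_bound <- function(x, default) {
  if (is.null(x) || is.na(x) || !nzchar(trimws(x))) return(default)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop("parse error: bad bound value '", x, "'")
  v
}

parse_reaction_equation <- function(eq, rid) {
  reversible <- grepl("<=>", eq, fixed = TRUE)
  arrow <- if (reversible) "<=>" else "=>"
  if (!grepl(arrow, eq, fixed = TRUE))
    stop("parse error: reaction '", rid, "' equation lacks '=>' arrow: ", eq)
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric())
    out <- numeric()
    for (term in trimws(strsplit(side, "+", fixed = TRUE)[[1]])) {
      if (!nzchar(term)) next
      bits <- strsplit(term, "\\s+")[[1]]
      if (length(bits) == 1L) { coef <- 1; met <- bits }
      else if (length(bits) == 2L) {
        coef <- suppressWarnings(as.numeric(bits[1]))
        if (is.na(coef))
          stop("parse error: reaction '", rid, "' bad term '", term, "'")
        met <- bits[2]
      } else stop("parse error: reaction '", rid, "' bad term '", term, "'")
      out[met] <- (if (is.na(out[met])) 0 else out[met]) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], 1)
  s <- lhs
  for (m in names(rhs)) s[m] <- (if (is.na(s[m])) 0 else s[m]) + rhs[m]
  s <- s[s != 0]
  if (!length(s))
    stop("parse error: reaction '", rid, "' has empty stoichiometry")
  list(stoich = s, reversible = reversible)
}

format_reaction_equation <- function(stoich, reversible) {
  lhs <- stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  fmt <- function(s, flip) {
    if (!length(s)) return("")
    paste(vapply(seq_along(s), function(i) {
      coef <- if (flip) -s[i] else s[i]
      if (coef == 1) names(s)[i] else paste(num17(coef), names(s)[i])
    }, character(1)), collapse = " + ")
  }
  paste(fmt(lhs, TRUE), if (reversible) "<=>" else "=>", fmt(rhs, FALSE))
}

num17 <- function(x) sprintf("%.17g", x)

#' @rdname tabular_io
#' @param model A \code{gem} object.
#' @export
write_gem_tabular <- function(model, path) {
  validate_gem(model)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# gem tabular dialect v1",
               paste0("# model: ", model$id),
               "[metabolites]",
               "id\tname\tcompartment"), con)
  writeLines(paste(model$mets$id, model$mets$name, model$mets$compartment,
                   sep = "\t"), con)
  writeLines(c("[reactions]", "id\tequation\tlb\tub\tgpr\tobjective"), con)
  for (i in seq_len(nrow(model$rxns))) {
    rid <- model$rxns$id[i]
    writeLines(paste(rid,
                     format_reaction_equation(model$stoich[[rid]],
                                              model$rxns$lb[i] < 0),
                     num17(model$rxns$lb[i]),
                     num17(model$rxns$ub[i]),
                     model$rxns$gpr[i],
                     as.integer(rid == model$objective),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Load or save a metabolic model
#'
#' Front door over the two supported on-disk formats: SBML Level 3 with the
#' fbc package, and the sectioned tabular dialect (see [read_gem_tabular()]).
#' \code{format = "auto"} decides by file extension (\code{.xml}/\code{.sbml}
#' vs anything else).
#'
#' @param path File path.
#' @param format One of \code{"auto"}, \code{"sbml"}, \code{"tabular"}.
#' @return A \code{gem} object.
#' @export
load_model <- function(path, format = c("auto", "sbml", "tabular")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "tabular"
  switch(format,
         sbml = read_gem_sbml(path),
         tabular = read_gem_tabular(path))
}

#' @rdname load_model
#' @param model A \code{gem} object.
#' @export
save_model <- function(model, path, format = c("auto", "sbml", "tabular")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "tabular"
  switch(format,
         sbml = write_gem_sbml(model, path),
         tabular = write_gem_tabular(model, path))
}
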