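#' Read a metabolic model from SBML Level 3 (fbc)
#'
#' Compact reader for the SBML subset constraint-based models use: species,
#' reactions with stoichiometry, flux bounds via fbc flux-bound parameters,
#' nested fbc gene-product associations, and the active fbc objective.
#' Conventional \code{M_}/\code{R_}/\code{G_} id prefixes (added by
#' [write_gem_sbml()]) are stripped on read.
#'
#' @param path Path to an SBML file.
#' @return A \code{gem} object.
#' @export
read_gem_sbml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  mnode <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mnode, "xml_missing"))
    stop("parse error in ", path, ": no <model> element")
  model_id <- xml2::xml_attr(mnode, "id")
  if (is.na(model_id)) model_id <- tools::file_path_sans_ext(basename(path))

  strip <- function(x, prefix) ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)

  sp <- xml2::xml_find_all(mnode, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp)) stop("parse error in ", path, ": no species declared")
  mets <- data.frame(
    id = strip(xml2::xml_attr(sp, "id"), "M_"),
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]
  mets$compartment[is.na(mets$compartment)] <- "c"

  pars <- xml2::xml_find_all(mnode, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  # gene product label lookup
  gps <- xml2::xml_find_all(mnode, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gplab <- stats::setNames(xml2::xml_attr(gps, "label"),
                           xml2::xml_attr(gps, "id"))
  gplab[is.na(gplab)] <- strip(names(gplab)[is.na(gplab)], "G_")

  gpa_to_string <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      lab <- if (!is.na(ref) && ref %in% names(gplab)) gplab[[ref]] else strip(ref, "G_")
      return(lab)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpa_to_string, character(1))
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  rnodes <- xml2::xml_find_all(mnode, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rnodes)) stop("parse error in ", path, ": no reactions declared")
  n <- length(rnodes)
  rid <- strip(xml2::xml_attr(rnodes, "id"), "R_")
  lb <- ub <- numeric(n)
  gpr <- character(n)
  stoich <- vector("list", n)
  for (i in seq_len(n)) {
    node <- rnodes[[i]]
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lbp <- xml2::xml_attr(node, "lowerFluxBound")
    ubp <- xml2::xml_attr(node, "upperFluxBound")
    lb[i] <- if (!is.na(lbp) && lbp %in% names(parval)) parval[[lbp]] else if (rev) -1000 else 0
    ub[i] <- if (!is.na(ubp) && ubp %in% names(parval)) parval[[ubp]] else 1000
    s <- numeric()
    for (ref in xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)) {
      met <- strip(xml2::xml_attr(ref, "species"), "M_")
      coef <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
      if (is.na(coef)) coef <- 1
      s[met] <- (if (is.na(s[met])) 0 else s[met]) - coef
    }
    for (ref in xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)) {
      met <- strip(xml2::xml_attr(ref, "species"), "M_")
      coef <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
      if (is.na(coef)) coef <- 1
      s[met] <- (if (is.na(s[met])) 0 else s[met]) + coef
    }
    if (!length(s))
      stop("parse error in ", path, ": reaction '", rid[i], "' has no stoichiometry")
    stoich[[i]] <- s
    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    gpr[i] <- if (inherits(gpa, "xml_missing")) "" else {
      root <- xml2::xml_children(gpa)
      if (length(root)) gpa_to_string(root[[1]]) else ""
    }
  }
  names(stoich) <- rid

  fobj <- xml2::xml_find_first(
    mnode, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  if (inherits(fobj, "xml_missing"))
    stop("configuration error in ", path, ": no fbc objective declared")
  objective <- strip(xml2::xml_attr(fobj, "reaction"), "R_")

  gem(id = model_id,
      metabolites = mets,
      reactions = data.frame(id = rid, lb = lb, ub = ub, gpr = gpr,
                             stringsAsFactors = FALSE),
      stoichiometry = stoich,
      objective = objective)
}

#' Write a metabolic model to SBML Level 3 (fbc)
#'
#' Emits species, compartments, per-reaction flux-bound parameters, nested
#' fbc gene-product associations, gene products, and the active maximize
#' objective, with conventional \code{M_}/\code{R_}/\code{G_} id prefixes.
#'
#' @param model A \code{gem} object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_gem_sbml <- function(model, path) {
  validate_gem(model)
  xml_escape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  gpa_xml <- function(node) {
    if (node$op == "gene")
      return(sprintf("<fbc:geneProductRef fbc:geneProduct=\"G_%s\"/>", xml_escape(node$gene)))
    inner <- paste(vapply(node$args, gpa_xml, character(1)), collapse = "")
    sprintf("<fbc:%s>%s</fbc:%s>", node$op, inner, node$op)
  }
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "xmlns:fbc=\"http://www.sbml.org/sbml/level3/version1/fbc/version2\" ",
           "level=\"3\" version=\"1\" fbc:required=\"false\">"),
    sprintf("<model id=\"%s\" fbc:strict=\"true\">", xml_escape(model$id)),
    "<listOfCompartments>",
    sprintf("<compartment id=\"%s\" constant=\"true\"/>",
            xml_escape(unique(model$mets$compartment))),
    "</listOfCompartments>",
    "<listOfSpecies>",
    sprintf(paste0("<species id=\"M_%s\" name=\"%s\" compartment=\"%s\" ",
                   "hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" constant=\"false\"/>"),
            xml_escape(model$mets$id), xml_escape(model$mets$name),
            xml_escape(model$mets$compartment)),
    "</listOfSpecies>",
    "<listOfParameters>",
    sprintf("<parameter id=\"P_lb_%s\" value=\"%s\" constant=\"true\"/>",
            xml_escape(model$rxns$id), num17(model$rxns$lb)),
    sprintf("<parameter id=\"P_ub_%s\" value=\"%s\" constant=\"true\"/>",
            xml_escape(model$rxns$id), num17(model$rxns$ub)),
    "</listOfParameters>",
    "<listOfReactions>")
  for (i in seq_len(nrow(model$rxns))) {
    rid <- model$rxns$id[i]
    s <- model$stoich[[rid]]
    out <- c(out, sprintf(paste0(
      "<reaction id=\"R_%s\" reversible=\"%s\" fast=\"false\" ",
      "fbc:lowerFluxBound=\"P_lb_%s\" fbc:upperFluxBound=\"P_ub_%s\">"),
      xml_escape(rid), if (model$rxns$lb[i] < 0) "true" else "false",
      xml_escape(rid), xml_escape(rid)))
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) out <- c(out, "<listOfReactants>",
      sprintf("<speciesReference species=\"M_%s\" stoichiometry=\"%s\" constant=\"true\"/>",
              xml_escape(names(reac)), num17(-reac)),
      "</listOfReactants>")
    if (length(prod)) out <- c(out, "<listOfProducts>",
      sprintf("<speciesReference species=\"M_%s\" stoichiometry=\"%s\" constant=\"true\"/>",
              xml_escape(names(prod)), num17(prod)),
      "</listOfProducts>")
    if (!is.null(model$gprs[[i]]))
      out <- c(out, "<fbc:geneProductAssociation>", gpa_xml(model$gprs[[i]]),
               "</fbc:geneProductAssociation>")
    out <- c(out, "</reaction>")
  }
  genes <- model_genes(model)
  out <- c(out,
    "</listOfReactions>",
    "<fbc:listOfObjectives fbc:activeObjective=\"obj\">",
    "<fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
    "<fbc:listOfFluxObjectives>",
    sprintf("<fbc:fluxObjective fbc:reaction=\"R_%s\" fbc:coefficient=\"1\"/>",
            xml_escape(model$objective)),
    "</fbc:listOfFluxObjectives>",
    "</fbc:objective>",
    "</fbc:listOfObjectives>",
    if (length(genes)) c("<fbc:listOfGeneProducts>",
      sprintf("<fbc:geneProduct fbc:id=\"G_%s\" fbc:label=\"%s\"/>",
              xml_escape(genes), xml_escape(genes)),
      "</fbc:listOfGeneProducts>"),
    "</model>",
    "</sbml>")
  writeLines(out, path)
  invisible(path)
}
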