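#' Read a genome-scale metabolic model from SBML (Level 3 + FBC)
#'
#' Supports the subset of SBML Level 3 with the FBC (flux balance
#' constraints) package that constraint-based models from standard
#' repositories use: species/reactions with stoichiometries, flux bounds
#' given as FBC parameters, an active FBC objective, and FBC gene-product
#' associations (nested and/or). Bounds are mandatory: a reaction without
#' both FBC flux-bound attributes is an error rather than silently defaulted.
#'
#' @param path path to an SBML file.
#' @return a `metabolic_model`.
#' @seealso [write_sbml()], [read_model_json()]
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML: ", conditionMessage(e)))
  ns <- xml2::xml_ns(doc)
  root <- xml2::xml_name(xml2::xml_root(doc))
  if (!identical(root, "sbml")) stop("malformed SBML: root element is <", root, ">, expected <sbml>")
  xml2::xml_ns_strip(doc)

  model_node <- xml2::xml_find_first(doc, ".//model")
  if (is.na(xml2::xml_name(model_node))) stop("malformed SBML: no <model> element")
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- basename(path)

  # parameters (flux bound values)
  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                             xml2::xml_attr(pars, "id"))

  # species (skip boundary-condition species: they are not balanced)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_id <- xml2::xml_attr(sp, "id")
  sp_bc <- xml2::xml_attr(sp, "boundaryCondition")
  mets <- sp_id[is.na(sp_bc) | sp_bc != "true"]
  if (!length(mets)) stop("malformed SBML: no (non-boundary) <species>")

  # gene products: id -> label (fbc-prefixed elements need local-name())
  gp <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  gp_lab <- stats::setNames(xml2::xml_attr(gp, "label"), xml2::xml_attr(gp, "id"))
  gp_lab[is.na(gp_lab)] <- names(gp_lab)[is.na(gp_lab)]

  gpr_of <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      id <- xml2::xml_attr(node, "geneProduct")
      lab <- gp_lab[id]
      return(if (is.na(lab)) id else unname(lab))
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpr_of, character(1))
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rx)) stop("malformed SBML: no <reaction> elements")
  nr <- length(rx)
  ids <- xml2::xml_attr(rx, "id")
  lb <- ub <- numeric(nr)
  gpr <- character(nr)
  S <- matrix(0, length(mets), nr, dimnames = list(mets, ids))
  for (i in seq_len(nr)) {
    r <- rx[[i]]
    lbp <- xml2::xml_attr(r, "lowerFluxBound")
    ubp <- xml2::xml_attr(r, "upperFluxBound")
    if (is.na(lbp) || is.na(ubp))
      stop("SBML reaction '", ids[i], "' lacks FBC flux bounds")
    if (!(lbp %in% names(par_val)) || !(ubp %in% names(par_val)))
      stop("SBML reaction '", ids[i], "' references undefined bound parameter")
    lb[i] <- par_val[lbp]; ub[i] <- par_val[ubp]
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(r, paste0("./", side, "/speciesReference"))
      if (length(refs)) {
        sid <- xml2::xml_attr(refs, "species")
        st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
        st[is.na(st)] <- 1
        if (side == "listOfReactants") st <- -st
        idx <- match(sid, mets)
        ok <- !is.na(idx)   # boundary species fall out of the balance
        S[idx[ok], i] <- S[idx[ok], i] + st[ok]
      }
    }
    ga <- xml2::xml_find_first(r, "./*[local-name()='geneProductAssociation']")
    gpr[i] <- if (is.na(xml2::xml_name(ga))) "" else {
      g <- gpr_of(xml2::xml_child(ga))
      sub("^\\((.*)\\)$", "\\1", g)
    }
  }

  obj_ref <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  if (is.na(xml2::xml_name(obj_ref))) stop("malformed SBML: no FBC objective")
  objective <- xml2::xml_attr(obj_ref, "reaction")

  metabolic_model(model_id, S, lb, ub, objective, gpr = gpr)
}

#' Write a metabolic model as SBML Level 3 + FBC v2
#'
#' Emits the minimal strict-FBC document that [read_sbml()] (and standard
#' constraint-based tooling) can read back: distinct bound parameters per
#' unique bound value, an active maximisation objective, and GPR rules as
#' nested and/or gene-product associations.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  vals <- sort(unique(c(model$lb, model$ub)))
  pid <- stats::setNames(paste0("fb_", seq_along(vals)), sprintf("%.17g", vals))
  pref <- function(v) unname(pid[sprintf("%.17g", v)])

  genes <- model_genes(model)
  gid <- stats::setNames(paste0("G_", make.names(genes)), genes)

  gpr_xml <- function(rule) {
    rule <- trimws(rule)
    if (rule == "") return(character(0))
    tokens <- .gpr_tokens(rule)
    node <- .gpr_parse(tokens)
    render <- function(nd) {
      if (nd$type == "gene")
        return(sprintf('<fbc:geneProductRef fbc:geneProduct="%s"/>', gid[nd$id]))
      tag <- if (nd$type == "and") "fbc:and" else "fbc:or"
      paste0("<", tag, ">", paste(vapply(nd$args, render, character(1)), collapse = ""),
             "</", tag, ">")
    }
    paste0("<fbc:geneProductAssociation>", render(node), "</fbc:geneProductAssociation>")
  }

  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false">')
  w('<model id="', esc(model$id), '" fbc:strict="true">')
  w('<listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>')
  w('<listOfSpecies>')
  for (m in model$metabolites)
    w('<species id="', esc(m), '" compartment="c" hasOnlySubstanceUnits="false" ',
      'boundaryCondition="false" constant="false"/>')
  w('</listOfSpecies>')
  w('<listOfParameters>')
  for (i in seq_along(vals))
    w('<parameter id="', pid[i], '" value="', sprintf("%.17g", vals[i]),
      '" constant="true"/>')
  w('</listOfParameters>')
  w('<listOfReactions>')
  for (i in seq_along(model$reactions)) {
    col <- model$S[, i]
    w('<reaction id="', esc(model$reactions[i]), '" reversible="',
      if (model$lb[i] < 0) "true" else "false",
      '" fast="false" fbc:lowerFluxBound="', pref(model$lb[i]),
      '" fbc:upperFluxBound="', pref(model$ub[i]), '">')
    rr <- which(col < 0); pp <- which(col > 0)
    if (length(rr)) {
      w('<listOfReactants>')
      for (k in rr) w('<speciesReference species="', esc(model$metabolites[k]),
                      '" stoichiometry="', sprintf("%.17g", -col[k]),
                      '" constant="true"/>')
      w('</listOfReactants>')
    }
    if (length(pp)) {
      w('<listOfProducts>')
      for (k in pp) w('<speciesReference species="', esc(model$metabolites[k]),
                      '" stoichiometry="', sprintf("%.17g", col[k]),
                      '" constant="true"/>')
      w('</listOfProducts>')
    }
    g <- gpr_xml(model$gpr[i])
    if (length(g)) w(g)
    w('</reaction>')
  }
  w('</listOfReactions>')
  w('<fbc:listOfObjectives fbc:activeObjective="obj">')
  w('<fbc:objective fbc:id="obj" fbc:type="maximize">')
  w('<fbc:listOfFluxObjectives><fbc:fluxObjective fbc:reaction="',
    esc(model$objective), '" fbc:coefficient="1"/></fbc:listOfFluxObjectives>')
  w('</fbc:objective></fbc:listOfObjectives>')
  if (length(genes)) {
    w('<fbc:listOfGeneProducts>')
    for (g in genes)
      w('<fbc:geneProduct fbc:id="', gid[g], '" fbc:label="', esc(g), '"/>')
    w('</fbc:listOfGeneProducts>')
  }
  w('</model>')
  w('</sbml>')
  invisible(path)
}
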