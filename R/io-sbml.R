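# SBML Level 3 Version 1 + fbc version 2 reader/writer (xml2-based).
# Covers the subset this package emits: compartments, species with chemical
# formulas, reactions with stoichiometry, flux-bound parameters, gene
# product associations, and a maximization objective. Identifiers are
# prefixed M_/R_/G_ on write and stripped on read, following common SBML
# practice. Pathway and source-tag metadata travel in reaction notes.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a model to SBML Level 3 with fbc flux bounds
#'
#' @param model a [MetabolicModel-class].
#' @param path output path.
#' @export
writeModelSBML <- function(model, path) {
  rx <- model@reactions
  gene_ids <- genes(model)
  bnd_vals <- sort(unique(c(rx$lb, rx$ub)))
  bnd_id <- function(v) paste0("bnd_", gsub("[^0-9A-Za-z]", "_", format(v, trim = TRUE)))

  ln <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" level="3" version="1" xmlns:fbc="%s" ',
                   'fbc:required="false">'), SBML_NS, FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', xmlEscape(model@id)),
    '    <listOfCompartments>')
  for (i in seq_len(nrow(model@compartments))) {
    cc <- model@compartments[i, ]
    ln <- c(ln, sprintf(
      '      <compartment id="%s" name="%s" spatialDimensions="3" size="1" constant="true"/>',
      cc$id, xmlEscape(paste0(cc$label, ":", cc$species_index))))
  }
  ln <- c(ln, '    </listOfCompartments>', '    <listOfSpecies>')
  for (i in seq_len(nrow(model@metabolites))) {
    mm <- model@metabolites[i, ]
    extra <- ""
    if (!is.na(mm$formula))
      extra <- paste0(extra, sprintf(' fbc:chemicalFormula="%s"', mm$formula))
    if (!is.na(mm$charge))
      extra <- paste0(extra, sprintf(' fbc:charge="%d"', mm$charge))
    ln <- c(ln, sprintf(
      paste0('      <species id="M_%s" name="%s" compartment="%s" ',
             'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
             'constant="false"%s/>'),
      mm$id, xmlEscape(mm$name), mm$compartment, extra))
  }
  ln <- c(ln, '    </listOfSpecies>', '    <listOfParameters>')
  for (v in bnd_vals)
    ln <- c(ln, sprintf(
      '      <parameter id="%s" value="%s" constant="true"/>',
      bnd_id(v), format(v, trim = TRUE)))
  ln <- c(ln, '    </listOfParameters>')
  if (length(gene_ids)) {
    ln <- c(ln, '    <fbc:listOfGeneProducts>')
    for (g in gene_ids)
      ln <- c(ln, sprintf(
        '      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>', g, xmlEscape(g)))
    ln <- c(ln, '    </fbc:listOfGeneProducts>')
  }
  ln <- c(ln, '    <listOfReactions>')
  gprXML <- function(tree, indent) {
    pad <- strrep(" ", indent)
    if (is.character(tree))
      return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>', pad, tree))
    tag <- if (tree$op == "and") "fbc:and" else "fbc:or"
    c(sprintf("%s<%s>", pad, tag),
      unlist(lapply(tree$args, gprXML, indent = indent + 2)),
      sprintf("%s</%s>", pad, tag))
  }
  for (i in seq_len(nrow(rx))) {
    st <- reactionStoich(model, rx$id[i])
    ln <- c(ln, sprintf(
      paste0('      <reaction id="R_%s" name="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      rx$id[i], xmlEscape(rx$name[i]), tolower(rx$lb[i] < 0),
      bnd_id(rx$lb[i]), bnd_id(rx$ub[i])))
    note <- sprintf('source_tag: %s', rx$source_tag[i])
    if (!is.na(rx$pathway[i]))
      note <- c(note, sprintf('pathway: %s', rx$pathway[i]))
    ln <- c(ln,
      '        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
      sprintf('          <p>%s</p>', xmlEscape(note)),
      '        </body></notes>')
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      ln <- c(ln, '        <listOfReactants>',
              sprintf('          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                      names(reac), format(-unname(reac), trim = TRUE)),
              '        </listOfReactants>')
    }
    if (length(prod)) {
      ln <- c(ln, '        <listOfProducts>',
              sprintf('          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                      names(prod), format(unname(prod), trim = TRUE)),
              '        </listOfProducts>')
    }
    tree <- parseGPR(rx$gpr[i])
    if (!is.null(tree)) {
      ln <- c(ln, '        <fbc:geneProductAssociation>',
              gprXML(tree, 10), '        </fbc:geneProductAssociation>')
    }
    ln <- c(ln, '      </reaction>')
  }
  ln <- c(ln, '    </listOfReactions>')
  if (length(model@biomassIds)) {
    ln <- c(ln,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      '        <fbc:listOfFluxObjectives>',
      sprintf('          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
              model@biomassIds),
      '        </fbc:listOfFluxObjectives>',
      '      </fbc:objective>',
      '    </fbc:listOfObjectives>')
  }
  ln <- c(ln, '  </model>', '</sbml>')
  writeLines(ln, path)
  invisible(path)
}

stripPrefix <- function(x, prefix) sub(paste0("^", prefix), "", x)

#' Read a model from SBML Level 3 with fbc flux bounds
#'
#' @param path SBML file path.
#' @return a [MetabolicModel-class].
#' @export
readModelSBML <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  mid <- xml2::xml_attr(mdl, "id")

  cnodes <- xml2::xml_find_all(doc, ".//s:listOfCompartments/s:compartment", ns)
  cname <- xml2::xml_attr(cnodes, "name")
  lab <- sub(":.*$", "", cname)
  spi <- suppressWarnings(as.integer(sub("^.*:", "", cname)))
  cmp <- data.frame(id = xml2::xml_attr(cnodes, "id"),
                    label = ifelse(is.na(lab) | lab == "", "cytosol", lab),
                    species_index = ifelse(is.na(spi), 0L, spi),
                    stringsAsFactors = FALSE)

  snodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = stripPrefix(xml2::xml_attr(snodes, "id"), "M_"),
    name = xml2::xml_attr(snodes, "name"),
    formula = xml2::xml_attr(snodes, "fbc:chemicalFormula", ns),
    charge = suppressWarnings(as.integer(xml2::xml_attr(snodes, "fbc:charge", ns))),
    compartment = xml2::xml_attr(snodes, "compartment"),
    stringsAsFactors = FALSE
  )

  pnodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pvals <- setNames(as.numeric(xml2::xml_attr(pnodes, "value")),
                    xml2::xml_attr(pnodes, "id"))

  rnodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxl <- vector("list", length(rnodes))
  stl <- vector("list", length(rnodes))
  parseAssoc <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef")
      return(stripPrefix(xml2::xml_attr(node, "fbc:geneProduct", ns), "G_"))
    kids <- xml2::xml_children(node)
    list(op = nm, args = lapply(kids, parseAssoc))
  }
  for (k in seq_along(rnodes)) {
    nd <- rnodes[[k]]
    rid <- stripPrefix(xml2::xml_attr(nd, "id"), "R_")
    notes <- xml2::xml_text(xml2::xml_find_all(
      nd, ".//s:notes//*[local-name() = 'p']", ns))
    tagline <- grep("^source_tag:", trimws(unlist(strsplit(notes, "\n"))), value = TRUE)
    pwline <- grep("^pathway:", trimws(unlist(strsplit(notes, "\n"))), value = TRUE)
    reac <- xml2::xml_find_all(nd, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(nd, "./s:listOfProducts/s:speciesReference", ns)
    st <- rbind(
      if (length(reac)) data.frame(
        reaction = rid,
        metabolite = stripPrefix(xml2::xml_attr(reac, "species"), "M_"),
        coef = -as.numeric(xml2::xml_attr(reac, "stoichiometry")),
        stringsAsFactors = FALSE),
      if (length(prod)) data.frame(
        reaction = rid,
        metabolite = stripPrefix(xml2::xml_attr(prod, "species"), "M_"),
        coef = as.numeric(xml2::xml_attr(prod, "stoichiometry")),
        stringsAsFactors = FALSE)
    )
    assoc <- xml2::xml_find_first(nd, "./fbc:geneProductAssociation", ns)
    gpr <- ""
    if (!inherits(assoc, "xml_missing")) {
      kids <- xml2::xml_children(assoc)
      if (length(kids)) gpr <- deparseGPR(parseAssoc(kids[[1]]))
    }
    rxl[[k]] <- data.frame(
      id = rid, name = xml2::xml_attr(nd, "name"),
      lb = unname(pvals[xml2::xml_attr(nd, "fbc:lowerFluxBound", ns)]),
      ub = unname(pvals[xml2::xml_attr(nd, "fbc:upperFluxBound", ns)]),
      gpr = gpr,
      pathway = if (length(pwline)) sub("^pathway: *", "", pwline[1]) else NA_character_,
      source_tag = if (length(tagline)) sub("^source_tag: *", "", tagline[1]) else "draft",
      stringsAsFactors = FALSE)
    stl[[k]] <- st
  }
  bio <- stripPrefix(xml2::xml_attr(
    xml2::xml_find_all(doc, ".//fbc:fluxObjective", ns), "fbc:reaction", ns), "R_")
  MetabolicModel(mid, cmp, mets, do.call(rbind, rxl), do.call(rbind, stl),
                 biomassIds = bio)
}
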