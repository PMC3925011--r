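## Lightweight SBML (Level 3 Version 1 subset) reader/writer on xml2.
## Species carry the component count in the "aioflux:carbon" attribute of
## their notes block and free-balance species are flagged with
## boundaryCondition="true"; roles are recovered from exchange-reaction
## topology on read.

#' Write a model as SBML
#'
#' @param model A [metabolic_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    sprintf('  <model id="%s" name="%s">', make.names(model$name),
            esc(model$name)),
    '    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    "    <listOfSpecies>")
  free_bal <- attr(model, "free_balance")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    lines <- c(lines, sprintf(
      '      <species id="%s" name="%s" compartment="c" constant="false" boundaryCondition="%s" hasOnlySubstanceUnits="false" aioflux:carbon="%.12g" aioflux:role="%s" xmlns:aioflux="https://aioflux/ns"/>',
      m$id, esc(m$name), tolower(m$id %in% free_bal), m$carbon, m$role))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfReactions>")
  for (r in model$reactions) {
    lines <- c(lines, sprintf(
      '      <reaction id="%s" name="%s" reversible="false" fast="false">',
      r$id, esc(r$name)))
    if (length(r$substrates)) {
      lines <- c(lines, "        <listOfReactants>",
                 sprintf('          <speciesReference species="%s" stoichiometry="%.12g" constant="true"/>',
                         names(r$substrates), r$substrates),
                 "        </listOfReactants>")
    }
    if (length(r$products)) {
      lines <- c(lines, "        <listOfProducts>",
                 sprintf('          <speciesReference species="%s" stoichiometry="%.12g" constant="true"/>',
                         names(r$products), r$products),
                 "        </listOfProducts>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

#' Read a model from SBML
#'
#' Reads the SBML subset this package writes (Level 2/3 core: species,
#' reactions, stoichiometric reactants/products, `boundaryCondition`).
#' Metabolite roles are derived from exchange-reaction topology (a species
#' produced by a reaction with no reactants is an input, one consumed by a
#' reaction with no products is an output) or taken from the
#' `aioflux:role` annotation when present; component counts are read from
#' `aioflux:carbon` (0 when absent).
#'
#' @param path SBML file path.
#' @return A [metabolic_model()].
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed SBML in ", path, ": ", conditionMessage(e),
         call. = FALSE))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing"))
    stop("malformed SBML: no <model> element in ", path, call. = FALSE)
  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp_nodes))
    stop("malformed SBML: no <species> in ", path, call. = FALSE)
  ids <- xml2::xml_attr(sp_nodes, "id")
  if (anyNA(ids)) stop("malformed SBML: species without id", call. = FALSE)
  carb <- suppressWarnings(as.numeric(xml2::xml_attr(sp_nodes, "carbon")))
  carb[is.na(carb)] <- 0
  nm <- xml2::xml_attr(sp_nodes, "name"); nm[is.na(nm)] <- ids[is.na(nm)]
  bc <- xml2::xml_attr(sp_nodes, "boundaryCondition")
  free_bal <- ids[!is.na(bc) & bc == "true"]
  mets <- Map(function(id, name, carbon)
    metabolite(id, name, carbon = carbon), ids, nm, carb)

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  reactions <- lapply(rx_nodes, function(node) {
    rid <- xml2::xml_attr(node, "id")
    if (is.na(rid)) stop("malformed SBML: reaction without id", call. = FALSE)
    rev <- xml2::xml_attr(node, "reversible")
    if (!is.na(rev) && rev == "true")
      stop("reaction ", rid, " is reversible: split it into two ",
           "irreversible reactions", call. = FALSE)
    pick <- function(which) {
      refs <- xml2::xml_find_all(
        node, sprintf("./s:listOf%s/s:speciesReference", which), ns)
      if (!length(refs)) return(numeric())
      sto <- suppressWarnings(as.numeric(xml2::xml_attr(refs, "stoichiometry")))
      sto[is.na(sto)] <- 1
      stats::setNames(sto, xml2::xml_attr(refs, "species"))
    }
    reaction(rid, pick("Reactants"), pick("Products"),
             name = { n <- xml2::xml_attr(node, "name")
                      if (is.na(n)) rid else n })
  })
  model <- metabolic_model(mets, reactions,
                           name = { n <- xml2::xml_attr(mdl, "name")
                                    if (is.na(n)) "sbml model" else n },
                           free_balance = free_bal)
  ## honour explicit role annotations when they are present
  role_attr <- xml2::xml_attr(sp_nodes, "role")
  if (any(!is.na(role_attr))) {
    idx <- match(ids, model$metabolites$id)
    ok <- !is.na(role_attr)
    model$metabolites$role[idx[ok]] <- role_attr[ok]
  }
  model
}
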