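# SBML Level 3 export/import of reaction networks, with mass-action kinetic
# laws carrying the statistical factors.

.sbml_ns <- "http://www.sbml.org/sbml/level3/version2/core"

.mathml_rate <- function(rate_ref, factor, reactants) {
  terms <- c(sprintf("<ci> %s </ci>", rate_ref),
             sprintf("<cn type=\"integer\"> %d </cn>", as.integer(factor)))
  for (nm in names(reactants)) {
    st <- reactants[[nm]]
    terms <- c(terms, if (st == 1) sprintf("<ci> %s </ci>", nm)
               else sprintf(paste0("<apply><power/><ci> %s </ci>",
                                   "<cn type=\"integer\"> %d </cn></apply>"),
                            nm, as.integer(st)))
  }
  paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
         "<apply><times/>", paste(terms, collapse = ""), "</apply></math>")
}

#' Export a reaction network as SBML Level 3
#'
#' Writes an SBML L3V2 document with one compartment, all species, the base
#' rate constants as parameters, and one reaction per network reaction with
#' a mass-action kinetic law `k * factor * prod(reactant^stoich)`.
#'
#' @param network A `prx_network` (mass-action reactions only).
#' @param params [kinetic_parameters()] supplying the base rate constants.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(network, params, path) {
  bad <- grepl("[^A-Za-z0-9_]", network$species$id)
  if (any(bad))
    stop("invalid SBML species identifiers: ",
         paste(network$species$id[bad], collapse = ", "), call. = FALSE)
  if (any(vapply(network$reactions, `[[`, "", "kind") == "trr_turnover"))
    stop("only mass-action networks can be exported to SBML; the TRR ",
         "turnover step uses a saturating rate law", call. = FALSE)
  refs <- unique(vapply(network$reactions, `[[`, "", "rate_ref"))
  for (r in refs)
    if (is.null(params[[r]]))
      stop("rate constant ", sQuote(r), " is not set", call. = FALSE)

  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<sbml xmlns=\"%s\" level=\"3\" version=\"2\">", .sbml_ns),
    "<model id=\"prxcycle_network\">",
    "<listOfCompartments>",
    "<compartment id=\"cell\" spatialDimensions=\"3\" size=\"1\" constant=\"true\"/>",
    "</listOfCompartments>",
    "<listOfSpecies>")
  lines <- c(lines, sprintf(paste0(
    "<species id=\"%s\" compartment=\"cell\" initialConcentration=\"0\" ",
    "hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" ",
    "constant=\"false\"/>"), network$species$id))
  lines <- c(lines, "</listOfSpecies>", "<listOfParameters>")
  lines <- c(lines, sprintf(
    "<parameter id=\"%s\" value=\"%.17g\" constant=\"true\"/>",
    refs, vapply(refs, function(r) params[[r]], 0)))
  lines <- c(lines, "</listOfParameters>", "<listOfReactions>")
  for (r in network$reactions) {
    lines <- c(lines, sprintf(
      "<reaction id=\"%s\" reversible=\"false\" sboTerm=\"SBO:0000012\">",
      r$id))
    lines <- c(lines, "<listOfReactants>", sprintf(
      "<speciesReference species=\"%s\" stoichiometry=\"%g\" constant=\"true\"/>",
      names(r$reactants), r$reactants), "</listOfReactants>")
    lines <- c(lines, "<listOfProducts>", sprintf(
      "<speciesReference species=\"%s\" stoichiometry=\"%g\" constant=\"true\"/>",
      names(r$products), r$products), "</listOfProducts>")
    lines <- c(lines,
               "<kineticLaw>",
               .mathml_rate(r$rate_ref, r$factor, r$reactants),
               "</kineticLaw>",
               paste0("<annotation><prxcycle kind=\"", r$kind,
                      "\" factor=\"", r$factor, "\"/></annotation>"),
               "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
  # validate well-formedness before writing
  doc <- xml2::read_xml(paste(lines, collapse = "\n"))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a reaction network from SBML written by [export_sbml()]
#'
#' Reconstructs species, stoichiometries, statistical factors and
#' rate-constant references, so that the re-derived mass-action right-hand
#' side can be compared against the native network.
#'
#' @param path SBML file.
#' @return List with `network` (a `prx_network`) and `parameters` (named
#'   vector of base rate constants).
#' @export
read_sbml_network <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = .sbml_ns)
  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  ids <- xml2::xml_attr(sp_nodes, "id")
  role <- ifelse(grepl("^Dec__", ids), "decamer",
          ifelse(grepl("^Prx_", ids), "dimer",
          ifelse(ids %in% SMALL_SPECIES, "small", "assay")))
  par_nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pars <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                          xml2::xml_attr(par_nodes, "id"))
  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  reactions <- lapply(rx_nodes, function(nd) {
    get_side <- function(which) {
      refs <- xml2::xml_find_all(
        nd, sprintf("./s:%s/s:speciesReference", which), ns)
      stats::setNames(as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      xml2::xml_attr(refs, "species"))
    }
    ann <- xml2::xml_find_first(nd, "./s:annotation/*", ns)
    math_cis <- xml2::xml_find_all(
      nd, "./s:kineticLaw//*[local-name()='ci']", ns)
    ci <- trimws(xml2::xml_text(math_cis))
    rate_ref <- setdiff(ci, c(names(get_side("listOfReactants")),
                              names(get_side("listOfProducts"))))[1]
    .rxn(xml2::xml_attr(nd, "id"),
         xml2::xml_attr(ann, "kind"),
         rate_ref,
         as.integer(xml2::xml_attr(ann, "factor")),
         get_side("listOfReactants"), get_side("listOfProducts"))
  })
  list(network = reaction_network(.mk_species(ids, role), reactions),
       parameters = pars)
}
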