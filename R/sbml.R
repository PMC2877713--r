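# SBML Level 3 export of compiled reaction networks, for interoperability
# with external simulators (COPASI etc.). Mass-action kinetic laws are
# written as explicit MathML products.

.mathml_product <- function(rate_name, reactants) {
  cis <- c(rate_name, rep(names(reactants), times = reactants))
  if (length(cis) == 1)
    inner <- paste0("<ci> ", cis, " </ci>")
  else
    inner <- paste0("<apply><times/>",
                    paste0("<ci> ", cis, " </ci>", collapse = ""),
                    "</apply>")
  paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
         inner, "</math>")
}

#' Export a reaction network as SBML Level 3
#'
#' Writes species (constant inputs flagged `constant="true"`), global
#' parameters, and reactions with mass-action kinetic laws into an SBML L3V2
#' core document.
#'
#' @param network a `reaction_network`.
#' @param path output file.
#' @param model_id model identifier (default `"operonet_model"`).
#' @return `path`, invisibly.
#' @export
write_sbml <- function(network, path, model_id = "operonet_model") {
  stopifnot(inherits(network, "reaction_network"))
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version2/core\"",
           " level=\"3\" version=\"2\">"),
    sprintf("  <model id=\"%s\">", esc(model_id)),
    "    <listOfCompartments>",
    "      <compartment id=\"cell\" size=\"1\" constant=\"true\"/>",
    "    </listOfCompartments>",
    "    <listOfSpecies>")
  for (sp in network$species) {
    const <- sp %in% network$constant_species
    lines <- c(lines, sprintf(
      paste0("      <species id=\"%s\" compartment=\"cell\"",
             " initialConcentration=\"%.17g\" hasOnlySubstanceUnits=\"false\"",
             " boundaryCondition=\"%s\" constant=\"%s\"/>"),
      esc(sp), network$initial[[sp]],
      if (const) "true" else "false", if (const) "true" else "false"))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  for (pn in names(network$parameters))
    lines <- c(lines, sprintf(
      "      <parameter id=\"%s\" value=\"%.17g\" constant=\"true\"/>",
      esc(pn), network$parameters[[pn]]))
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    lines <- c(lines, sprintf(
      "      <reaction id=\"r%d\" reversible=\"false\">", j))
    if (length(r$reactants)) {
      lines <- c(lines, "        <listOfReactants>")
      for (sp in names(r$reactants))
        lines <- c(lines, sprintf(
          "          <speciesReference species=\"%s\" stoichiometry=\"%d\" constant=\"true\"/>",
          esc(sp), r$reactants[[sp]]))
      lines <- c(lines, "        </listOfReactants>")
    }
    if (length(r$products)) {
      lines <- c(lines, "        <listOfProducts>")
      for (sp in names(r$products))
        lines <- c(lines, sprintf(
          "          <speciesReference species=\"%s\" stoichiometry=\"%d\" constant=\"true\"/>",
          esc(sp), r$products[[sp]]))
      lines <- c(lines, "        </listOfProducts>")
    }
    lines <- c(lines,
               "        <kineticLaw>",
               paste0("          ", .mathml_product(r$rate_name, r$reactants)),
               "        </kineticLaw>",
               "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(lines, path)
  # validate well-formedness
  invisible(xml2::read_xml(path))
  invisible(path)
}

#' Read the reaction layer back from an operonet SBML file
#'
#' Round-trips the documents written by [write_sbml()]: species, constants,
#' parameters and reaction stoichiometries (kinetic laws are assumed
#' mass-action with the named rate parameter).
#'
#' @param path SBML file.
#' @return a `reaction_network`-like list with `species`, `reactions`,
#'   `parameters`, `constant_species`, `initial` (no compiled gene metadata).
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version2/core")
  spn <- xml2::xml_find_all(doc, ".//s:species", ns)
  species <- xml2::xml_attr(spn, "id")
  const <- species[xml2::xml_attr(spn, "constant") == "true"]
  initial <- setNames(as.numeric(xml2::xml_attr(spn, "initialConcentration")),
                      species)
  pn <- xml2::xml_find_all(doc, ".//s:parameter", ns)
  params <- setNames(as.numeric(xml2::xml_attr(pn, "value")),
                     xml2::xml_attr(pn, "id"))
  reactions <- lapply(xml2::xml_find_all(doc, ".//s:reaction", ns), function(rn) {
    get_side <- function(tag) {
      refs <- xml2::xml_find_all(rn, sprintf(".//s:%s/s:speciesReference", tag), ns)
      setNames(as.integer(xml2::xml_attr(refs, "stoichiometry")),
               xml2::xml_attr(refs, "species"))
    }
    kl <- xml2::xml_find_first(rn, ".//s:kineticLaw", ns)
    cis <- xml2::xml_text(xml2::xml_find_all(kl, ".//*[local-name()='ci']"))
    rate_name <- trimws(cis[1])
    list(reactants = get_side("listOfReactants"),
         products = get_side("listOfProducts"),
         rate_name = rate_name, rate_value = unname(params[rate_name]))
  })
  structure(list(species = species, reactions = reactions,
                 parameters = params, constant_species = const,
                 initial = initial, genes = list(), semantics = NA_character_,
                 graph = NULL),
            class = "reaction_network")
}
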