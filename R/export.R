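# Serialization of the network model: JSON (round-trippable), SBML Level 3
# Version 2 (mass-action kinetic laws, uM and seconds), and GraphML for the
# species-metabolite reaction graph.

#' Export a network model
#'
#' @param model a \code{pghs_network}.
#' @param file output path.
#' @param format \code{"json"}, \code{"sbml"} or \code{"graphml"}.
#' @return the file path, invisibly.
#' @export
export_network <- function(model, file, format = c("json", "sbml", "graphml")) {
  format <- match.arg(format)
  switch(format,
         json = .export_json(model, file),
         sbml = .export_sbml(model, file),
         graphml = .export_graphml(model, file))
  invisible(file)
}

.export_json <- function(model, file) {
  obj <- list(
    format = "pghsnet-model",
    version = 1L,
    policy = model$policy,
    profile = attr(model$params, "profile"),
    parameters = as.list(structure(as.numeric(model$params),
                                   names = names(model$params))),
    species = model$species,
    reactions = model$reactions)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
}

#' Import a network model from JSON
#'
#' Inverse of the JSON export: \code{import_network(export_network(m))}
#' reproduces the species, reaction and parameter lists exactly.
#'
#' @param file path to a JSON model document.
#' @return a \code{pghs_network}.
#' @export
import_network <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "pghsnet-model")
    stop("not a pghsnet model document")
  params <- as_pghs_parameters(unlist(obj$parameters), profile = obj$profile)
  sp <- as.data.frame(obj$species, stringsAsFactors = FALSE)
  rownames(sp) <- sp$label
  rx <- as.data.frame(obj$reactions, stringsAsFactors = FALSE)
  rx$paper_id <- as.integer(rx$paper_id)
  structure(list(species = sp, reactions = rx, params = params,
                 policy = obj$policy),
            class = "pghs_network")
}

# --- SBML -------------------------------------------------------------------

.sbml_species_id <- function(lab) {
  if (!length(lab)) return(character(0))
  paste0("S_", lab)
}

.mathml_times <- function(doc_ns, factors) {
  # <apply><times/> ci ci ... </apply> (or a single <ci>)
  if (length(factors) == 1)
    return(paste0("<ci> ", factors, " </ci>"))
  paste0("<apply><times/>",
         paste0("<ci> ", factors, " </ci>", collapse = ""), "</apply>")
}

.export_sbml <- function(model, file) {
  rx <- model$reactions
  esc <- function(x) gsub("&", "&amp;", x)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">',
    '<model id="pghs1_cycle_network" name="PGHS-1 cycle network" substanceUnits="uM" timeUnits="second" extentUnits="uM">',
    '<listOfUnitDefinitions>',
    '<unitDefinition id="uM"><listOfUnits><unit kind="mole" exponent="1" scale="-6" multiplier="1"/><unit kind="litre" exponent="-1" scale="0" multiplier="1"/></listOfUnits></unitDefinition>',
    '</listOfUnitDefinitions>',
    '<listOfCompartments><compartment id="cell" size="1" constant="true"/></listOfCompartments>',
    '<listOfSpecies>')
  all_sp <- c(model$species$label, .metab_names)
  lines <- c(lines, vapply(all_sp, function(s) sprintf(
    '<species id="%s" name="%s" compartment="cell" initialConcentration="0" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
    .sbml_species_id(s), esc(s)), character(1)))
  lines <- c(lines, '</listOfSpecies>', '<listOfParameters>')
  lines <- c(lines, vapply(seq_along(model$params), function(i) sprintf(
    '<parameter id="%s" value="%.17g" constant="true"/>',
    names(model$params)[i], as.numeric(model$params[i])), character(1)))
  # reverse binding constants as derived koff parameters
  for (i in which(rx$reversible))
    lines <- c(lines, sprintf('<parameter id="koff_r%d" value="%.17g" constant="true"/>',
                              rx$id[i], rx$rev_rate[i]))
  lines <- c(lines, '</listOfParameters>', '<listOfReactions>')

  metab_delta <- function(r) {
    d <- c(AA = r$dAA, O2 = r$dO2, RC = r$dRC, OC = r$dOC, PGG2 = r$dPGG2,
           PGH2 = r$dPGH2, SINK = r$dSink)
    d[d != 0]
  }
  for (i in seq_len(nrow(rx))) {
    r <- rx[i, ]
    d <- metab_delta(r)
    reac <- c(structure(1, names = r$reactant), -d[d < 0])
    prod <- c(structure(1, names = r$product), d[d > 0])
    sref <- function(v) paste0(vapply(seq_along(v), function(j) sprintf(
      '<speciesReference species="%s" stoichiometry="%g" constant="true"/>',
      .sbml_species_id(names(v)[j]), v[j]), character(1)), collapse = "")
    cons <- d[d < 0]
    fwd_factors <- c(r$rate_name, .sbml_species_id(r$reactant),
                     rep(.sbml_species_id(names(cons)), unname(-cons)))
    law <- .mathml_times(NULL, fwd_factors)
    if (r$reversible) {
      rev_factors <- c(paste0("koff_r", r$id), .sbml_species_id(r$product))
      law <- paste0("<apply><minus/>", law,
                    .mathml_times(NULL, rev_factors), "</apply>")
    }
    lines <- c(lines, sprintf(
      '<reaction id="r%d" name="%s:%s-%s" reversible="%s">', r$id,
      r$template, r$reactant, r$product, tolower(as.character(r$reversible))),
      paste0("<listOfReactants>", sref(reac), "</listOfReactants>"),
      paste0("<listOfProducts>", sref(prod), "</listOfProducts>"),
      paste0('<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
             law, "</math></kineticLaw>"),
      "</reaction>")
  }
  lines <- c(lines, '</listOfReactions>', '</model>', '</sbml>')
  doc <- xml2::read_xml(paste(lines, collapse = "\n"))  # well-formedness gate
  xml2::write_xml(doc, file)
}

# --- GraphML ----------------------------------------------------------------

.export_graphml <- function(model, file) {
  rx <- model$reactions
  # enzyme-transition edges, annotated with template / rate / source number
  e_edges <- data.frame(from = rx$reactant, to = rx$product,
                        template = rx$template, rate_name = rx$rate_name,
                        rate = rx$rate,
                        paper_id = ifelse(is.na(rx$paper_id), -1L, rx$paper_id),
                        stringsAsFactors = FALSE)
  # metabolite participation edges (consumed -> into reaction's product node;
  # produced <- out of the reactant node)
  m_edges <- list()
  for (i in seq_len(nrow(rx))) {
    d <- c(AA = rx$dAA[i], O2 = rx$dO2[i], RC = rx$dRC[i], OC = rx$dOC[i],
           PGG2 = rx$dPGG2[i], PGH2 = rx$dPGH2[i])
    for (m in names(d[d < 0]))
      m_edges[[length(m_edges) + 1]] <- data.frame(
        from = m, to = rx$product[i], template = rx$template[i],
        rate_name = "consumed", rate = -d[[m]], paper_id = -1L,
        stringsAsFactors = FALSE)
    for (m in names(d[d > 0]))
      m_edges[[length(m_edges) + 1]] <- data.frame(
        from = rx$reactant[i], to = m, template = rx$template[i],
        rate_name = "produced", rate = d[[m]], paper_id = -1L,
        stringsAsFactors = FALSE)
  }
  edges <- rbind(e_edges, do.call(rbind, m_edges))
  nodes <- data.frame(
    name = c(model$species$label, setdiff(.metab_names, "SINK")),
    kind = c(model$species$kind, rep("metabolite", 6)),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  igraph::write_graph(g, file, format = "graphml")
}
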