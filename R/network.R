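# Composition-driven reaction templates of the PGHS-1 cycle network.
#
# Every reaction converts exactly one enzyme species into one enzyme species
# (the enzyme moiety is conserved), optionally consuming/producing the six
# metabolites AA, O2, RC, OC, PGG2, PGH2 and routing discarded COX-site
# ligands to an explicit damage sink on inactivation. Fourteen templates
# cover the network: G1-G11 (catalysis) and S1-S3 (self-inactivation).

.canon_order <- c(paste0("E", 1:24), "D1", "D2", "D3", "FIE")

# helper: one reaction record (metabolite deltas are for the forward direction)
.rx <- function(template, reactant, product, rate_name, rate,
                paper_id = NA_integer_, reversible = FALSE, rev_rate = 0,
                dAA = 0, dO2 = 0, dRC = 0, dOC = 0, dPGG2 = 0, dPGH2 = 0,
                dSink = 0) {
  data.frame(template = template, reactant = reactant, product = product,
             rate_name = rate_name, rate = rate,
             paper_id = as.integer(paper_id), reversible = reversible,
             rev_rate = rev_rate, dAA = dAA, dO2 = dO2, dRC = dRC, dOC = dOC,
             dPGG2 = dPGG2, dPGH2 = dPGH2, dSink = dSink,
             stringsAsFactors = FALSE)
}

# paper reaction numbers, where the text names one, keyed by reactant label
.paper_ids <- list(
  G1  = c(E5 = 1, E15 = 5, E11 = 47),
  G2  = c(E1 = 31, E2 = 32, E3 = 30),
  G3  = c(E9 = 2, E20 = 6, E19 = 64),
  G4  = c(E13 = 3, E16 = 7, E21 = 33),
  G5  = c(E8 = 4, E12 = 8, E7 = 52),
  G6  = c(E1 = 11, E14 = 16, E16 = 20, E12 = 23, D1 = 25),
  G7  = c(E2 = 12, D2 = 26),
  G8  = c(E3 = 10, E5 = 19, E8 = 22, E9 = 28, E13 = 29, D3 = 27),
  G9  = c(E5 = 9, E4 = 49, E15 = 50, E9 = 14, E20 = 51),
  G10 = c(E2 = 13, E10 = 18),
  G11 = c(E10 = 56),
  S1  = c(E2 = 38, E11 = 39, E19 = 40, E21 = 41, D2 = 42, E7 = 53,
          E10 = 54, E23 = 67),
  S2  = c(E5 = 43, E9 = 44, E15 = 45, E20 = 46),
  S3  = c(E17 = 36, E4 = 37, E5 = 58, E9 = 59, E11 = 60, E15 = 61,
          E19 = 62, E20 = 68)
)

.pid <- function(template, reactant) {
  v <- .paper_ids[[template]]
  if (!is.null(v) && reactant %in% names(v)) as.integer(v[[reactant]])
  else NA_integer_
}

# instantiate one template over the species table; returns a reaction data.frame
.apply_template <- function(template, sp, p) {
  cat_sp <- sp[sp$kind == "catalytic", , drop = FALSE]
  dead_sp <- sp[sp$kind == "cox_dead", , drop = FALSE]
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- .rx(template, ...)

  if (template == "G1") {
    # reversible AA binding to Tyr*-bearing empty-site catalytic states
    for (i in which(cat_sp$tyr == "TyrRad" & cat_sp$site == "empty")) {
      s <- cat_sp[i, ]
      add(s$label, .species_label(s$heme, s$tyr, "AA"), "k1", p[["k1"]],
          paper_id = .pid("G1", s$label), reversible = TRUE,
          rev_rate = p[["k1"]] * p[["Kd1"]], dAA = -1)
    }
  } else if (template == "G2") {
    # reversible AA binding to ground-Tyr empty-site catalytic states
    for (i in which(cat_sp$tyr == "Tyr" & cat_sp$site == "empty")) {
      s <- cat_sp[i, ]
      add(s$label, .species_label(s$heme, s$tyr, "AA"), "k12", p[["k12"]],
          paper_id = .pid("G2", s$label), reversible = TRUE,
          rev_rate = p[["k12"]] * p[["Kd12"]], dAA = -1)
    }
  } else if (template == "G3") {
    # H abstraction by Tyr385*: Tyr* + AA -> Tyr + AA*
    for (i in which(cat_sp$tyr == "TyrRad" & cat_sp$site == "AA")) {
      s <- cat_sp[i, ]
      add(s$label, .species_label(s$heme, "Tyr", "AArad"), "k2", p[["k2"]],
          paper_id = .pid("G3", s$label))
    }
  } else if (template == "G4") {
    # oxygenation: AA* + 2 O2 -> PGG2* (O2 enters squared in the rate law)
    for (i in which(cat_sp$site == "AArad")) {
      s <- cat_sp[i, ]
      add(s$label, .species_label(s$heme, s$tyr, "PGG2rad"), "k3", p[["k3"]],
          paper_id = .pid("G4", s$label), dO2 = -2)
    }
  } else if (template == "G5") {
    # PGG2 release regenerating Tyr385*: [.., Tyr, PGG2*] -> [.., Tyr*, empty] + PGG2
    for (i in which(cat_sp$tyr == "Tyr" & cat_sp$site == "PGG2rad")) {
      s <- cat_sp[i, ]
      add(s$label, .species_label(s$heme, "TyrRad", "empty"), "k4", p[["k4"]],
          paper_id = .pid("G5", s$label), dPGG2 = 1)
    }
  } else if (template == "G6") {
    # peroxidase step: Fe(III) + PGG2 -> Fe(IV),PP*+ + PGH2
    for (i in which(cat_sp$heme == "FeIII_PP")) {
      s <- cat_sp[i, ]
      add(s$label, .species_label("FeIV_PPrad", s$tyr, s$site), "k7",
          p[["k7"]], paper_id = .pid("G6", s$label), dPGG2 = -1, dPGH2 = 1)
    }
    for (i in which(dead_sp$heme == "FeIII_PP")) {
      s <- dead_sp[i, ]
      add(s$label, dead_sp$label[dead_sp$heme == "FeIV_PPrad"], "k7",
          p[["k7"]], paper_id = .pid("G6", s$label), dPGG2 = -1, dPGH2 = 1)
    }
  } else if (template == "G7") {
    # PP*+ reduction by RC: Fe(IV),PP*+ + RC -> Fe(IV),PP + OC
    for (i in which(cat_sp$heme == "FeIV_PPrad")) {
      s <- cat_sp[i, ]
      add(s$label, .species_label("FeIV_PP", s$tyr, s$site), "k8", p[["k8"]],
          paper_id = .pid("G7", s$label), dRC = -1, dOC = 1)
    }
    for (i in which(dead_sp$heme == "FeIV_PPrad")) {
      s <- dead_sp[i, ]
      add(s$label, dead_sp$label[dead_sp$heme == "FeIV_PP"], "k8", p[["k8"]],
          paper_id = .pid("G7", s$label), dRC = -1, dOC = 1)
    }
  } else if (template == "G8") {
    # ferryl reduction by RC: Fe(IV),PP + RC -> Fe(III),PP + OC
    for (i in which(cat_sp$heme == "FeIV_PP")) {
      s <- cat_sp[i, ]
      add(s$label, .species_label("FeIII_PP", s$tyr, s$site), "k6", p[["k6"]],
          paper_id = .pid("G8", s$label), dRC = -1, dOC = 1)
    }
    for (i in which(dead_sp$heme == "FeIV_PP")) {
      s <- dead_sp[i, ]
      add(s$label, dead_sp$label[dead_sp$heme == "FeIII_PP"], "k6", p[["k6"]],
          paper_id = .pid("G8", s$label), dRC = -1, dOC = 1)
    }
  } else if (template == "G9") {
    # Tyr* reduction by RC; the rate depends on COX-site occupancy:
    # k5 for empty or PGG2*-occupied sites, k10 when arachidonate (AA/AA*)
    # occupies the channel and hinders cosubstrate access
    for (i in which(cat_sp$tyr == "TyrRad")) {
      s <- cat_sp[i, ]
      rn <- if (s$site %in% c("empty", "PGG2rad")) "k5" else "k10"
      add(s$label, .species_label(s$heme, "Tyr", s$site), rn, p[[rn]],
          paper_id = .pid("G9", s$label), dRC = -1, dOC = 1)
    }
  } else if (template == "G10") {
    # intramolecular electron transfer: PP*+ + Tyr -> PP + Tyr*
    # (k9 with an empty COX site, k11 when the site is occupied)
    for (i in which(cat_sp$heme == "FeIV_PPrad" & cat_sp$tyr == "Tyr")) {
      s <- cat_sp[i, ]
      rn <- if (s$site == "empty") "k9" else "k11"
      add(s$label, .species_label("FeIV_PP", "TyrRad", s$site), rn, p[[rn]],
          paper_id = .pid("G10", s$label))
    }
  } else if (template == "G11") {
    # TC-route H abstraction by the porphyrin radical cation from bound AA:
    # [Fe(IV),PP*+ .., AA] -> [Fe(IV),PP .., AA*]
    for (i in which(cat_sp$heme == "FeIV_PPrad" & cat_sp$site == "AA")) {
      s <- cat_sp[i, ]
      add(s$label, .species_label("FeIV_PP", s$tyr, "AArad"), "k13",
          p[["k13"]], paper_id = .pid("G11", s$label))
    }
  } else if (template == "S1") {
    # full self-inactivation of any PP*+-bearing species (catalytic or
    # COX-dead); a bound ligand is discarded to the damage sink
    for (i in which(cat_sp$heme == "FeIV_PPrad")) {
      s <- cat_sp[i, ]
      add(s$label, "FIE", "kin1", p[["kin1"]], paper_id = .pid("S1", s$label),
          dSink = .site_moiety(s$site))
    }
    for (i in which(dead_sp$heme == "FeIV_PPrad")) {
      s <- dead_sp[i, ]
      add(s$label, "FIE", "kin1", p[["kin1"]], paper_id = .pid("S1", s$label))
    }
  } else if (template == "S2") {
    # full self-inactivation from the Intermediate-II-derived states
    for (lab in c("E5", "E9", "E15", "E20")) {
      s <- cat_sp[cat_sp$label == lab, ]
      add(s$label, "FIE", "kin2", p[["kin2"]], paper_id = .pid("S2", s$label),
          dSink = .site_moiety(s$site))
    }
  } else if (template == "S3") {
    # COX-site inactivation of any catalytic species carrying a radical in
    # the COX site (Tyr385* and/or AA*); the heme state is preserved and the
    # species becomes peroxidase-only (COX-dead)
    dead_of <- structure(dead_sp$label, names = dead_sp$heme)
    for (i in which(cat_sp$tyr == "TyrRad" | cat_sp$site == "AArad")) {
      s <- cat_sp[i, ]
      add(s$label, unname(dead_of[s$heme]), "kin", p[["kin"]],
          paper_id = .pid("S3", s$label), dSink = .site_moiety(s$site))
    }
  } else stop("unknown template ", template)

  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  # canonical, species-order-independent ordering within the template
  out[order(match(out$reactant, .canon_order)), , drop = FALSE]
}

.templates <- c(paste0("G", 1:11), paste0("S", 1:3))

#' Instantiate the PGHS-1 reaction list
#'
#' Applies the fourteen composition-driven reaction templates (G1-G11
#' catalysis, S1-S3 self-inactivation) to the enumerated species and binds
#' rate constants from a parameter set. Under the default
#' \code{"composition_complete"} policy every species matching a template
#' predicate reacts; under \code{"paper_enumerated"} only reactions carrying
#' an explicitly numbered counterpart in the source reaction scheme are
#' retained (a strict subset, provided for comparison).
#'
#' @param species species table from \code{\link{pghs_species}}.
#' @param params a \code{\link{pghs_parameters}} object (or coercible vector).
#' @param policy \code{"composition_complete"} or \code{"paper_enumerated"}.
#' @return a data.frame of reaction instances: \code{id}, \code{paper_id},
#'   \code{template}, \code{reactant}, \code{product}, \code{rate_name},
#'   forward \code{rate}, \code{reversible} flag and \code{rev_rate}
#'   (binding only, \code{koff = kon * Kd}), and signed metabolite deltas
#'   \code{dAA, dO2, dRC, dOC, dPGG2, dPGH2, dSink} for the forward direction.
#' @examples
#' rx <- pghs_reactions(pghs_species(), pghs_parameters())
#' subset(rx, paper_id == 1)   # E5 + AA <-> E9, kon 690, koff 69
#' @export
pghs_reactions <- function(species, params,
                           policy = c("composition_complete",
                                      "paper_enumerated")) {
  policy <- match.arg(policy)
  params <- as_pghs_parameters(params)
  p <- as.list(structure(as.numeric(params), names = names(params)))
  rx <- do.call(rbind, lapply(.templates, .apply_template, sp = species, p = p))
  if (policy == "paper_enumerated")
    rx <- rx[!is.na(rx$paper_id), , drop = FALSE]
  rx <- data.frame(id = seq_len(nrow(rx)), rx, stringsAsFactors = FALSE)
  rownames(rx) <- NULL
  rx
}

#' Build the PGHS-1 cycle-network model
#'
#' Convenience constructor assembling species, reactions and parameters into
#' a network model object, the input of \code{\link{pghs_simulate}}.
#'
#' @inheritParams pghs_reactions
#' @param params kinetic parameter set; defaults to \code{pghs_parameters()}.
#' @return an object of class \code{"pghs_network"} with elements
#'   \code{species}, \code{reactions}, \code{params}, \code{policy}.
#' @examples
#' net <- pghs_network()
#' net
#' @export
pghs_network <- function(params = pghs_parameters(),
                         policy = c("composition_complete",
                                    "paper_enumerated")) {
  policy <- match.arg(policy)
  params <- as_pghs_parameters(params)
  species <- pghs_species(policy)
  structure(list(species = species,
                 reactions = pghs_reactions(species, params, policy),
                 params = params, policy = policy),
            class = "pghs_network")
}

#' @export
print.pghs_network <- function(x, ...) {
  cat("PGHS-1 cycle-network model (", x$policy, ")\n", sep = "")
  cat("  species:  ", nrow(x$species), " (",
      sum(x$species$kind == "catalytic"), " catalytic, ",
      sum(x$species$kind == "cox_dead"), " COX-dead, 1 FIE)\n", sep = "")
  cat("  reactions:", nrow(x$reactions),
      sprintf("(%d reversible bindings, %d with source numbering)\n",
              sum(x$reactions$reversible), sum(!is.na(x$reactions$paper_id))))
  cat("  profile:  ", attr(x$params, "profile"), "\n", sep = "")
  invisible(x)
}

#' @export
summary.pghs_network <- function(object, ...) {
  tab <- table(object$reactions$template)
  cat("Reactions per template:\n")
  print(tab[order(match(names(tab), .templates))])
  invisible(validate_pghs_network(object, quiet = TRUE))
}

#' Restrict a network to a subset of reactions
#'
#' Retains only the reactions with the given source reaction numbers; used to
#' carve out small sub-networks (e.g. for oracle comparisons).
#'
#' @param model a \code{pghs_network}.
#' @param paper_ids integer vector of source reaction numbers to keep.
#' @return a \code{pghs_network} with the reduced reaction list.
#' @export
pghs_subnetwork <- function(model, paper_ids) {
  stopifnot(inherits(model, "pghs_network"))
  keep <- model$reactions$paper_id %in% paper_ids
  if (!any(keep)) stop("no reactions match the given ids")
  model$reactions <- model$reactions[keep, , drop = FALSE]
  model$reactions$id <- seq_len(nrow(model$reactions))
  rownames(model$reactions) <- NULL
  model
}

#' Structural diagnostics of a network model
#'
#' Checks (a) enzyme-moiety closure (every reaction maps exactly one enzyme
#' species to one enzyme species), (b) that FIE is absorbing, (c) directed
#' reachability of every species from the resting state E1, and (d) species
#' without outgoing catalytic reactions. Violations of (a) or (b) are hard
#' errors; (c)/(d) findings are reported as warnings in the returned object.
#'
#' @param model a \code{pghs_network}.
#' @param quiet suppress printing of the report.
#' @return (invisibly) a list of class \code{"pghs_network_report"} with
#'   elements \code{ok}, \code{unreachable}, \code{no_outgoing},
#'   \code{fie_outdegree}.
#' @export
validate_pghs_network <- function(model, quiet = FALSE) {
  stopifnot(inherits(model, "pghs_network"))
  rx <- model$reactions
  sp <- model$species$label
  if (!all(rx$reactant %in% sp) || !all(rx$product %in% sp))
    stop("enzyme-moiety closure violated: reaction references unknown species")
  fie_out <- sum(rx$reactant == "FIE")
  if (fie_out > 0) stop("FIE must be absorbing but has outgoing reactions")
  edges <- rbind(cbind(rx$reactant, rx$product),
                 cbind(rx$product[rx$reversible], rx$reactant[rx$reversible]))
  g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = TRUE,
                                     vertices = data.frame(name = sp))
  d <- igraph::distances(g, v = "E1", mode = "out")
  unreachable <- sp[is.infinite(d[1, sp])]
  catalytic_rx <- rx[!startsWith(rx$template, "S"), ]
  no_out <- setdiff(sp[model$species$kind != "fie"], catalytic_rx$reactant)
  rep <- structure(list(ok = length(unreachable) == 0, unreachable = unreachable,
                        no_outgoing = no_out, fie_outdegree = fie_out,
                        graph = g),
                   class = "pghs_network_report")
  if (!quiet) print(rep)
  invisible(rep)
}

#' @export
print.pghs_network_report <- function(x, ...) {
  cat("Network diagnostics:\n")
  cat("  FIE out-degree:", x$fie_outdegree, "\n")
  cat("  unreachable from E1:",
      if (length(x$unreachable)) paste(x$unreachable, collapse = ", ")
      else "none", "\n")
  cat("  no outgoing catalytic reaction:",
      if (length(x$no_outgoing)) paste(x$no_outgoing, collapse = ", ")
      else "none", "\n")
  invisible(x)
}
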