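# Microstate space of the PGHS-1 catalytic domain.
#
# A catalytic state is a composition of three components:
#   heme (POX site):  Fe(III),PP | Fe(IV),PP*+ | Fe(IV),PP
#   Tyr385:           ground | tyrosyl radical
#   COX site:         empty | AA | AA* | PGG2*
# plus three COX-dead species (peroxidase-only, one per heme state) and the
# single absorbing fully-inactive-enzyme (FIE) species.

.heme_levels <- c("FeIII_PP", "FeIV_PPrad", "FeIV_PP")
.tyr_levels  <- c("Tyr", "TyrRad")
.site_levels <- c("empty", "AA", "AArad", "PGG2rad")

# canonical label for each of the 24 heme x tyr x site compositions
.canonical_states <- local({
  lab <- c(
    E1  = "FeIII_PP|Tyr|empty",      E2  = "FeIV_PPrad|Tyr|empty",
    E3  = "FeIV_PP|Tyr|empty",       E4  = "FeIV_PP|TyrRad|PGG2rad",
    E5  = "FeIV_PP|TyrRad|empty",    E6  = "FeIV_PP|Tyr|AA",
    E7  = "FeIV_PPrad|Tyr|PGG2rad",  E8  = "FeIV_PP|Tyr|PGG2rad",
    E9  = "FeIV_PP|TyrRad|AA",       E10 = "FeIV_PPrad|Tyr|AA",
    E11 = "FeIV_PPrad|TyrRad|empty", E12 = "FeIII_PP|Tyr|PGG2rad",
    E13 = "FeIV_PP|Tyr|AArad",       E14 = "FeIII_PP|Tyr|AA",
    E15 = "FeIII_PP|TyrRad|empty",   E16 = "FeIII_PP|Tyr|AArad",
    E17 = "FeIV_PP|TyrRad|AArad",    E18 = "FeIII_PP|TyrRad|AArad",
    E19 = "FeIV_PPrad|TyrRad|AA",    E20 = "FeIII_PP|TyrRad|AA",
    E21 = "FeIV_PPrad|Tyr|AArad",    E22 = "FeIV_PPrad|TyrRad|AArad",
    E23 = "FeIV_PPrad|TyrRad|PGG2rad", E24 = "FeIII_PP|TyrRad|PGG2rad")
  stopifnot(!anyDuplicated(lab), length(lab) == 24)
  lab
})

#' Enumerate the enzyme species of the PGHS-1 network
#'
#' Returns the 28-species state space of the model: 24 catalytic microstates
#' (every combination of 3 heme states, 2 Tyr385 states and 4 COX-site
#' occupancies, labelled E1..E24), 3 COX-dead peroxidase-only species (D1..D3,
#' one per heme state), and the absorbing fully inactive enzyme (FIE).
#' Labels are canonical and stable across runs.
#'
#' @param policy network-generation policy; the species set is identical under
#'   \code{"composition_complete"} and \code{"paper_enumerated"}.
#' @return a data.frame with columns \code{label}, \code{kind}
#'   (\code{catalytic}/\code{cox_dead}/\code{fie}), \code{heme}, \code{tyr},
#'   \code{site} (the last three are \code{NA} where not applicable).
#' @examples
#' sp <- pghs_species()
#' nrow(sp)                                     # 28
#' subset(sp, heme == "FeIII_PP" & tyr == "Tyr" & site == "empty")$label  # E1
#' @export
pghs_species <- function(policy = c("composition_complete", "paper_enumerated")) {
  match.arg(policy)
  comp <- expand.grid(heme = .heme_levels, tyr = .tyr_levels,
                      site = .site_levels, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  key <- paste(comp$heme, comp$tyr, comp$site, sep = "|")
  lab <- names(.canonical_states)[match(key, .canonical_states)]
  stopifnot(!anyNA(lab))
  cat24 <- data.frame(label = lab, kind = "catalytic", comp,
                      stringsAsFactors = FALSE)
  cat24 <- cat24[order(as.integer(sub("^E", "", cat24$label))), ]
  dead <- data.frame(label = c("D1", "D2", "D3"), kind = "cox_dead",
                     heme = .heme_levels, tyr = NA_character_,
                     site = NA_character_, stringsAsFactors = FALSE)
  fie <- data.frame(label = "FIE", kind = "fie", heme = NA_character_,
                    tyr = NA_character_, site = NA_character_,
                    stringsAsFactors = FALSE)
  out <- rbind(cat24, dead, fie)
  rownames(out) <- out$label
  out
}

# label of the catalytic species with the given composition
.species_label <- function(heme, tyr, site) {
  key <- paste(heme, tyr, site, sep = "|")
  lab <- names(.canonical_states)[match(key, .canonical_states)]
  if (anyNA(lab)) stop("no catalytic species with composition ", key)
  lab
}

# arachidonate-moiety count carried by a bound COX-site ligand
.site_moiety <- function(site) as.integer(site %in% c("AA", "AArad", "PGG2rad"))
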