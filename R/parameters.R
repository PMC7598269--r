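#' Unified kinetic parameter set of the PGHS-1 network model
#'
#' Constructs the set of 18 fitted rate constants that parameterise every
#' reaction of the cycle-network model. Defaults are the unified set obtained
#' by joint calibration against PGG2/PGH2 production, AA consumption and
#' adrenochrome accumulation kinetics. Two peroxidase profiles are available:
#' \code{"phenol_pgg2"} (phenol as reducing cosubstrate, PGG2 as peroxidase
#' substrate) and \code{"adrenaline_h2o2"} (adrenaline as cosubstrate, H2O2
#' driving the peroxidase cycle), which differ only in the peroxidase subset
#' \code{k5, k6, k7, k8}.
#'
#' Units: second-order constants in 1/(uM s) (\code{k3} in 1/(uM^2 s), oxygen
#' enters its reaction squared), first-order constants in 1/s, dissociation
#' constants \code{Kd1}, \code{Kd12} in uM. Unbinding rates are derived as
#' \code{koff = kon * Kd}.
#'
#' @param profile peroxidase-subset profile, \code{"phenol_pgg2"} (default) or
#'   \code{"adrenaline_h2o2"}.
#' @param ... named overrides of individual constants, e.g. \code{kin = 0}.
#' @return an object of class \code{"pghs_parameters"}: a named numeric vector
#'   of the 18 constants with the profile kept as an attribute.
#' @examples
#' p <- pghs_parameters()
#' p["k9"]                     # intramolecular electron transfer, 310 /s
#' pghs_parameters("adrenaline_h2o2")["k5"]
#' pghs_parameters(kin = 0, kin1 = 0, kin2 = 0)  # self-inactivation off
#' @export
pghs_parameters <- function(profile = c("phenol_pgg2", "adrenaline_h2o2"), ...) {
  profile <- match.arg(profile)
  p <- c(
    k1   = 690,    # AA binding to Tyr*-bearing empty COX site, 1/(uM s)
    Kd1  = 0.1,    # its dissociation constant, uM
    k2   = 2690,   # H abstraction Tyr* + AA -> Tyr + AA*, 1/s
    k3   = 173,    # oxygenation AA* + 2 O2 -> PGG2*, 1/(uM^2 s)
    k4   = 13,     # PGG2 release with Tyr* regeneration, 1/s
    k5   = 0.18,   # Tyr* reduction by RC (empty/PGG2* site), 1/(uM s)
    k6   = 0.58,   # ferryl Fe(IV)PP reduction by RC, 1/(uM s)
    k7   = 7.1,    # peroxidase step Fe(III) + PGG2 -> Fe(IV)PP*+ + PGH2, 1/(uM s)
    k8   = 0.001,  # Fe(IV)PP*+ reduction by RC, 1/(uM s)
    k9   = 310,    # intramolecular e- transfer PP*+ + Tyr (empty site), 1/s
    k10  = 0.1,    # Tyr* reduction by RC with AA in the COX site, 1/(uM s)
    k11  = 1.1,    # intramolecular e- transfer with occupied COX site, 1/s
    k12  = 690,    # AA binding to ground-Tyr empty-site states, 1/(uM s)
    Kd12 = 0.6,    # its dissociation constant, uM
    k13  = 18.8,   # TC-route H abstraction by PP*+ from bound AA, 1/s
    kin  = 0.72,   # COX-site self-inactivation (-> COX-dead), 1/s
    kin1 = 0.6,    # PP*+-driven full self-inactivation (-> FIE), 1/s
    kin2 = 2.5     # Intermediate-II-driven full self-inactivation (-> FIE), 1/s
  )
  if (profile == "adrenaline_h2o2")
    p[c("k5", "k6", "k7", "k8")] <- c(0.06, 0.001, 0.001, 0.001)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
      stop("unknown parameter override(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- vapply(dots, function(x) as.numeric(x)[1], numeric(1))
  }
  if (anyNA(p) || any(p < 0))
    stop("all kinetic parameters must be non-negative and finite")
  structure(p, profile = profile, class = "pghs_parameters")
}

#' @export
print.pghs_parameters <- function(x, ...) {
  cat("PGHS-1 kinetic parameter set (profile: ", attr(x, "profile"), ")\n", sep = "")
  print(unclass(structure(as.numeric(x), names = names(x))), ...)
  invisible(x)
}

# coerce user-supplied vectors/lists while preserving validation
as_pghs_parameters <- function(x, profile = NULL) {
  if (inherits(x, "pghs_parameters")) return(x)
  do.call(pghs_parameters,
          c(list(profile = if (is.null(profile)) "phenol_pgg2" else profile),
            as.list(x)))
}
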