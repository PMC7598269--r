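# Synthetic calibration fixtures emulating the three classes of kinetic
# datasets used to parameterise the model: prostaglandin production kinetics
# (phenol as cosubstrate), AA-consumption kinetics, and adrenochrome
# accumulation in the pure-peroxidase H2O2/adrenaline assay. Experimental
# curves of these classes exist only as published figures, so calibration is
# exercised against seeded synthetic data of the same shape.

#' Specification of a synthetic fixture
#'
#' Scenarios and their default condition blocks:
#' \describe{
#'   \item{PG_KINETICS}{PGG2 and PGH2 time courses at 35 nM enzyme, 80 uM AA
#'     and phenol at 100, 1000 and 5000 uM; span 1200 s.}
#'   \item{AA_CONSUMPTION}{AA time courses at 35 nM enzyme, 1000 uM phenol
#'     and AA at 0.5, 1, 2 and 20 uM; span 300 s.}
#'   \item{ADRENOCHROME}{oxidised-cosubstrate (adrenochrome) accumulation at
#'     35 nM enzyme, 1050 uM H2O2 and adrenaline at 0.32, 0.54, 1.08, 1.62,
#'     2.16 and 3.22 uM, no AA; span 300 s.}
#' }
#' Sampling times default to 10 points log-spaced over the scenario span.
#' Noise is multiplicative Gaussian with standard deviation \code{noise_sd}
#' (default 5\%), truncated at zero (concentration data carry
#' scale-proportional error).
#'
#' @param scenario one of \code{"PG_KINETICS"}, \code{"AA_CONSUMPTION"},
#'   \code{"ADRENOCHROME"}.
#' @param times sampling times (s); \code{NULL} for the scenario default.
#' @param noise_sd multiplicative noise standard deviation (fraction).
#' @param seed RNG seed for the noise.
#' @param conditions optional named list of condition blocks overriding the
#'   scenario defaults (see \code{\link{pghs_dataset}}).
#' @return object of class \code{"fixture_spec"}.
#' @export
fixture_spec <- function(scenario = c("PG_KINETICS", "AA_CONSUMPTION",
                                      "ADRENOCHROME"),
                         times = NULL, noise_sd = 0.05, seed = 1,
                         conditions = NULL) {
  scenario <- match.arg(scenario)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  defaults <- switch(scenario,
    PG_KINETICS = list(
      span = 1200,
      observables = c("PGG2", "PGH2"),
      conditions = stats::setNames(lapply(c(100, 1000, 5000), function(rc)
        list(enzyme_total = 0.035, AA = 80, RC = rc, H2O2 = 0,
             cosubstrate = "phenol")),
        paste0("phenol_", c(100, 1000, 5000)))),
    AA_CONSUMPTION = list(
      span = 300,
      observables = "AA",
      conditions = stats::setNames(lapply(c(0.5, 1, 2, 20), function(aa)
        list(enzyme_total = 0.035, AA = aa, RC = 1000, H2O2 = 0,
             cosubstrate = "phenol")),
        paste0("aa_", c(0.5, 1, 2, 20)))),
    ADRENOCHROME = list(
      span = 300,
      observables = "OC",
      conditions = stats::setNames(
        lapply(c(0.32, 0.54, 1.08, 1.62, 2.16, 3.22), function(rc)
          list(enzyme_total = 0.035, AA = 0, RC = rc, H2O2 = 1050,
               cosubstrate = "adrenaline")),
        paste0("adrenaline_", c(0.32, 0.54, 1.08, 1.62, 2.16, 3.22)))))
  if (is.null(times))
    times <- 10^seq(log10(defaults$span / 100), log10(defaults$span),
                    length.out = 10)
  if (is.unsorted(times, strictly = TRUE) || any(times <= 0))
    stop("sampling times must be positive and increasing")
  if (!is.null(conditions)) defaults$conditions <- conditions
  structure(list(scenario = scenario, times = times, noise_sd = noise_sd,
                 seed = seed, observables = defaults$observables,
                 conditions = defaults$conditions),
            class = "fixture_spec")
}

#' Generate a synthetic calibration dataset
#'
#' Simulates every condition block of the fixture specification with the
#' given parameters, samples the scenario's observable(s) at the specified
#' times, applies seeded truncated multiplicative Gaussian noise, and
#' (optionally) writes the dataset as CSV + YAML.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param params parameter set used as ground truth.
#' @param stem optional path stem; when given, \code{<stem>.csv} and
#'   \code{<stem>.yaml} are written via \code{\link{write_dataset}}.
#' @param override names of constants in \code{params} that should override
#'   the condition profile's own peroxidase defaults (relevant only for
#'   adrenaline/H2O2 blocks, whose k5..k8 otherwise come from that profile).
#' @param policy network policy.
#' @return a \code{\link{pghs_dataset}} (invisibly when \code{stem} is
#'   given).
#' @export
generate_fixtures <- function(spec, params = pghs_parameters(), stem = NULL,
                              override = character(),
                              policy = "composition_complete") {
  stopifnot(inherits(spec, "fixture_spec"))
  recs <- list()
  for (cid in names(spec$conditions)) {
    cond <- spec$conditions[[cid]]
    for (obs in spec$observables) {
      rec <- data.frame(condition_id = cid, observable = obs,
                        time_s = spec$times, value_uM = NA_real_, weight = 1,
                        stringsAsFactors = FALSE)
      rec$value_uM <- .predict_condition(params, cond, rec, policy, override)
      recs[[paste(cid, obs)]] <- rec
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  if (spec$noise_sd > 0) {
    z <- .with_seed(spec$seed,
                    function() stats::rnorm(nrow(records), 0, spec$noise_sd))
    records$value_uM <- pmax(0, records$value_uM * (1 + z))
  }
  ds <- pghs_dataset(records, spec$conditions)
  if (!is.null(stem)) {
    write_dataset(ds, stem)
    return(invisible(ds))
  }
  ds
}
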