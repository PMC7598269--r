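# Derived observables of the PGHS-1 model: oxygen-consumption kinetics,
# dose-response and apparent Michaelis constant, Eadie-Scatchard coordinates,
# activation threshold, consumption stoichiometry, and the flux table.

#' Oxygen-consumption rate time series
#'
#' \code{V_O2(t) = 2 x sum of oxygenation fluxes}: every oxygenation event
#' (AA* + 2 O2 -> PGG2*) consumes two oxygen molecules, so the oxygen
#' consumption rate is twice the summed flux of the G4 reactions.
#'
#' @param traj a \code{pghs_trajectory}.
#' @return numeric vector of V_O2 (uM/s) on the trajectory's time grid.
#' @export
oxygen_consumption_rate <- function(traj) {
  g4 <- which(traj$model$reactions$template == "G4")
  if (!length(g4)) stop("model contains no oxygenation (G4) reactions")
  2 * rowSums(traj$flux[, g4, drop = FALSE])
}

#' Duration of enzyme activity
#'
#' Width of the time interval on which \code{V_O2(t)} stays at or above a
#' fraction (default 5\%) of its maximum, with linear interpolation of the
#' crossing times.
#'
#' @param traj a \code{pghs_trajectory}.
#' @param frac threshold as a fraction of the V_O2 maximum.
#' @return width in seconds.
#' @export
activity_duration <- function(traj, frac = 0.05) {
  v <- oxygen_consumption_rate(traj)
  t <- traj$times
  th <- frac * max(v)
  above <- v >= th
  if (!any(above)) return(0)
  i1 <- which(above)[1]; i2 <- rev(which(above))[1]
  t_on <- if (i1 == 1) t[1] else
    stats::approx(v[(i1 - 1):i1], t[(i1 - 1):i1], xout = th)$y
  t_off <- if (i2 == length(t)) t[i2] else
    stats::approx(v[i2:(i2 + 1)], t[i2:(i2 + 1)], xout = th)$y
  t_off - t_on
}

#' Oxygen-consumption dose-response curve
#'
#' Runs one simulation per AA value at a fixed cosubstrate level and records
#' the maximum-over-time oxygen consumption rate.
#'
#' @param model a \code{pghs_network}.
#' @param aa_grid strictly increasing AA concentrations (uM).
#' @param rc cosubstrate concentration (uM).
#' @param config base \code{\link{pghs_config}}; AA and RC are overridden.
#' @return object of class \code{"pghs_dose_response"}: data.frame with
#'   columns \code{AA}, \code{rate} (max V_O2, uM/s), \code{failed}; the RC
#'   level and config are attached as attributes.
#' @export
dose_response <- function(model, aa_grid, rc, config = pghs_config(t_end = 100)) {
  if (any(aa_grid < 0) || is.unsorted(aa_grid, strictly = TRUE))
    stop("aa_grid must be non-negative and strictly increasing")
  rate <- numeric(length(aa_grid)); failed <- logical(length(aa_grid))
  for (i in seq_along(aa_grid)) {
    cfg <- config; cfg$AA <- aa_grid[i]; cfg$RC <- rc
    tr <- tryCatch(pghs_simulate(model, cfg), error = function(e) NULL)
    if (is.null(tr)) { failed[i] <- TRUE; rate[i] <- NA_real_ }
    else rate[i] <- if (aa_grid[i] == 0) 0 else max(oxygen_consumption_rate(tr))
  }
  structure(data.frame(AA = aa_grid, rate = rate, failed = failed),
            RC = rc, config = config, class = c("pghs_dose_response",
                                                "data.frame"))
}

#' Apparent Michaelis constant from a dose-response curve
#'
#' \code{Vmax} is the plateau of the curve (the maximum must lie within 5\%
#' of the rates at the last two grid points, otherwise the plateau is flagged
#' as not reached and \code{Km} is \code{NA}); \code{Km} is the AA value at
#' half of \code{Vmax} by monotone linear interpolation. The half-maximum
#' definition is used deliberately instead of a hyperbolic fit: at high
#' cosubstrate the curve is sigmoidal, so a Michaelis fit is mis-specified
#' while the half-maximum reading remains an operational "apparent" constant.
#'
#' @param curve a \code{pghs_dose_response} (or data.frame with AA, rate).
#' @return list with \code{Km} (uM), \code{Vmax} (uM/s), \code{plateau}
#'   (logical).
#' @export
apparent_km <- function(curve) {
  aa <- curve$AA; v <- curve$rate
  ok <- !is.na(v); aa <- aa[ok]; v <- v[ok]
  n <- length(v)
  if (n < 3) stop("need at least three usable grid points")
  vmax <- max(v)
  plateau <- all(vmax <= 1.05 * v[c(n - 1, n)])
  if (!plateau) return(list(Km = NA_real_, Vmax = vmax, plateau = FALSE))
  half <- vmax / 2
  i <- which(v >= half)[1]
  km <- if (i == 1) aa[1] else
    stats::approx(v[(i - 1):i], aa[(i - 1):i], xout = half)$y
  list(Km = km, Vmax = vmax, plateau = TRUE)
}

#' Eadie-Scatchard coordinates of a dose-response curve
#'
#' Transforms the curve to (V/E, V/AA/E) coordinates, in which Michaelis
#' kinetics is a straight line of slope -1/Km while positive cooperativity
#' produces the characteristic hooked, downward-concave point set (V/AA/E
#' first rises with V/E at the sigmoid foot, then falls). Two diagnostics
#' are attached: \code{deviation}, the maximal residual from the
#' least-squares line scaled by the data range (~0 for Michaelis kinetics),
#' and \code{concave}, \code{TRUE} when at least two thirds of the interior
#' second differences are strictly negative (downward concavity; a straight
#' line has none).
#'
#' @param curve a \code{pghs_dose_response}.
#' @param enzyme_total total enzyme (uM) used for the normalisation.
#' @return data.frame with columns \code{v_e} (= V_O2/E) and \code{v_aa_e}
#'   (= V_O2/AA/E), ordered by \code{v_e}, with attributes \code{concave},
#'   \code{deviation} and \code{second_differences}.
#' @export
eadie_scatchard <- function(curve, enzyme_total) {
  keep <- curve$AA > 0 & !is.na(curve$rate)
  aa <- curve$AA[keep]; v <- curve$rate[keep]
  v_e <- v / enzyme_total
  v_aa_e <- v / aa / enzyme_total
  o <- order(v_e)
  x <- v_e[o]; y <- v_aa_e[o]
  d2 <- diff(diff(y) / diff(x))          # slope change along the plot
  fit <- stats::lm.fit(cbind(1, x), y)
  dev <- max(abs(fit$residuals)) / max(diff(range(y)), .Machine$double.eps)
  tol <- 1e-6 * max(abs(y)) / max(abs(x))
  structure(data.frame(v_e = x, v_aa_e = y),
            concave = mean(d2 < -tol) >= 2 / 3, deviation = dev,
            second_differences = d2)
}

#' Activation-threshold curve in the (AA, RC) plane
#'
#' For each cosubstrate level, bisects on the AA axis for the lowest AA at
#' which PGH2 at \code{t_eval} reaches the criterion level. Below the curve
#' the autocatalytic COX machinery fails to ignite.
#'
#' @param model a \code{pghs_network}.
#' @param rc_grid cosubstrate levels (uM).
#' @param criterion PGH2 level defining activation (uM); default 0.02.
#' @param t_eval evaluation time (s); default 300 (past the activity burst).
#' @param aa_range AA search bracket (uM).
#' @param rel_tol relative bracket width at which bisection stops.
#' @param config base configuration (enzyme etc.).
#' @return data.frame with columns \code{RC}, \code{threshold_AA},
#'   \code{at_boundary} (criterion not bracketed: the reported value is the
#'   search bound).
#' @export
activation_threshold <- function(model, rc_grid, criterion = 0.02,
                                 t_eval = 300, aa_range = c(1e-3, 50),
                                 rel_tol = 0.01, config = pghs_config()) {
  if (criterion < 0) stop("criterion must be >= 0")
  pgh2_at <- function(aa, rc) {
    cfg <- config
    cfg$AA <- aa; cfg$RC <- rc
    cfg$times <- c(0, 10^seq(-3, log10(t_eval), length.out = 200))
    cfg$t_end <- t_eval
    tr <- pghs_simulate(model, cfg)
    tr$conc[nrow(tr$conc), "PGH2"]
  }
  out <- data.frame(RC = rc_grid, threshold_AA = NA_real_, at_boundary = FALSE)
  for (j in seq_along(rc_grid)) {
    lo <- aa_range[1]; hi <- aa_range[2]
    f_lo <- pgh2_at(lo, rc_grid[j]) - criterion
    if (f_lo >= 0) {            # already active at the lower search bound
      out$threshold_AA[j] <- lo; out$at_boundary[j] <- TRUE; next
    }
    f_hi <- pgh2_at(hi, rc_grid[j]) - criterion
    if (f_hi < 0) {             # criterion unreachable on the interval
      out$threshold_AA[j] <- hi; out$at_boundary[j] <- TRUE; next
    }
    while ((hi - lo) / hi > rel_tol) {
      mid <- sqrt(lo * hi)      # bisection in log-AA
      if (pgh2_at(mid, rc_grid[j]) >= criterion) hi <- mid else lo <- mid
    }
    out$threshold_AA[j] <- sqrt(lo * hi)
  }
  out
}

#' RC/AA consumption ratio at a time point
#'
#' \code{(RC0 - RC(t)) / (AA0 - AA(t))}, the stoichiometric coupling of
#' cosubstrate oxidation to arachidonate oxygenation. Complete conversion of
#' PGG2 to PGH2 would require two RC per AA (ratio 2); lower values indicate
#' PGG2 accumulating unconverted.
#'
#' @param traj a \code{pghs_trajectory}.
#' @param t evaluation time (s), within the trajectory span.
#' @return the ratio, or \code{NA} (with a warning) if less than 1e-9 uM of
#'   AA was consumed.
#' @export
consumption_ratio <- function(traj, t = 30) {
  tt <- traj$times
  if (t < tt[1] || t > tt[length(tt)]) stop("t outside the trajectory span")
  rc <- stats::approx(tt, traj$conc[, "RC"], xout = t)$y
  aa <- stats::approx(tt, traj$conc[, "AA"], xout = t)$y
  rc0 <- traj$config$RC; aa0 <- traj$config$AA
  if ((aa0 - aa) < 1e-9) {
    warning("AA consumption below 1e-9 uM; ratio undefined")
    return(NA_real_)
  }
  (rc0 - rc) / (aa0 - aa)
}

#' Flux table of the PGG2/PGH2-producing reactions
#'
#' One simulation per cosubstrate level; reports the maximum-over-time net
#' flux of the PGH2-producing peroxidase steps in the POX_1/POX_2/POX_4
#' cycles (reactions 11, 16, 23), the PGG2-release steps of the three COX
#' cycles (reactions 4, 8, 52) and the ferryl-reduction reactions connecting
#' the COX_1 and COX_2 cycles (reactions 22, 28, 29).
#'
#' @param model a \code{pghs_network}.
#' @param rc_levels cosubstrate concentrations (uM).
#' @param config base configuration (default: 35 nM enzyme, 80 uM AA,
#'   1200 s).
#' @param reactions source reaction numbers to report.
#' @return data.frame: one row per RC level, one column (\code{V<i>}) per
#'   reaction, entries in uM/s.
#' @export
flux_table <- function(model, rc_levels,
                       config = pghs_config(enzyme_total = 0.035, AA = 80,
                                            t_end = 1200),
                       reactions = c(11, 16, 23, 4, 8, 52, 22, 28, 29)) {
  if (any(rc_levels <= 0)) stop("RC levels must be positive")
  out <- matrix(NA_real_, length(rc_levels), length(reactions),
                dimnames = list(NULL, paste0("V", reactions)))
  for (i in seq_along(rc_levels)) {
    cfg <- config; cfg$RC <- rc_levels[i]
    tr <- pghs_simulate(model, cfg)
    fx <- reaction_flux(tr, reactions, paper_id = TRUE)
    out[i, ] <- apply(fx, 2, max)
  }
  data.frame(RC = rc_levels, out, check.names = FALSE)
}
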