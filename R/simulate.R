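# Mass-action ODE assembly and stiff integration of the cycle network.
#
# State vector (35 entries, all uM): the 28 enzyme species in canonical order
# (E1..E24, D1..D3, FIE), then the six metabolites AA, O2, RC, OC, PGG2, PGH2,
# and the damage sink collecting arachidonate moieties discarded on
# self-inactivation. Reaction fluxes are recomputed from the stored states
# after integration, not co-integrated.

.metab_names <- c("AA", "O2", "RC", "OC", "PGG2", "PGH2", "SINK")

.state_names <- function(model) c(model$species$label, .metab_names)

#' Simulation configuration
#'
#' Conditions of a single in vitro run. All concentrations are in uM and the
#' time span in seconds. By default the whole enzyme pool starts in the
#' resting state E1, the system is seeded with a trace of PGG2 (0.01 uM,
#' the peroxide tone required to ignite the autocatalytic cycle), and oxygen
#' starts at 200 uM (approximately air-saturated buffer; at the fitted
#' oxygenation constant it is never rate-limiting above ~50 uM).
#'
#' @param enzyme_total total enzyme (uM); default 0.035 (35 nM).
#' @param AA,O2,RC,OC,PGG2,PGH2 initial metabolite concentrations (uM).
#' @param o2_clamped hold O2 constant during the run.
#' @param t_end end of the integration span (s).
#' @param times explicit output grid (s); default: 0 plus 400 log-spaced
#'   points from 1 ms to \code{t_end} (sub-millisecond binding transients are
#'   below the reporting resolution).
#' @param rtol,atol relative/absolute solver tolerances.
#' @param hmax maximal internal step (s); \code{Inf} (default) lets the BDF
#'   integrator choose freely, which is accurate for the smooth mass-action
#'   right-hand side.
#' @param init optional named vector of initial enzyme-species concentrations
#'   (uM) overriding the all-in-E1 default; names must be species labels.
#' @return a list of class \code{"pghs_config"}.
#' @export
pghs_config <- function(enzyme_total = 0.035, AA = 80, O2 = 200, RC = 100,
                        OC = 0, PGG2 = 0.01, PGH2 = 0, o2_clamped = FALSE,
                        t_end = 1200, times = NULL, rtol = 1e-8, atol = 1e-10,
                        hmax = Inf, init = NULL) {
  conc <- c(enzyme_total = enzyme_total, AA = AA, O2 = O2, RC = RC, OC = OC,
            PGG2 = PGG2, PGH2 = PGH2)
  if (anyNA(conc) || any(conc < 0)) stop("concentrations must be >= 0")
  if (is.null(times)) {
    if (t_end <= 0) stop("t_end must be positive")
    times <- c(0, 10^seq(log10(1e-3), log10(t_end), length.out = 400))
  }
  if (is.unsorted(times, strictly = TRUE)) stop("time grid must be strictly increasing")
  structure(list(enzyme_total = enzyme_total, AA = AA, O2 = O2, RC = RC,
                 OC = OC, PGG2 = PGG2, PGH2 = PGH2, o2_clamped = o2_clamped,
                 t_end = max(times), times = times, rtol = rtol, atol = atol,
                 hmax = hmax, init = init),
            class = "pghs_config")
}

# compile the reaction list into channel index vectors + stoichiometry matrix
.compile_network <- function(model) {
  sn <- .state_names(model)
  idx <- structure(seq_along(sn), names = sn)
  rx <- model$reactions
  n_rx <- nrow(rx)

  # forward channels, then reverse channels of the reversible bindings
  rev_rows <- which(rx$reversible)
  k <- c(rx$rate, rx$rev_rate[rev_rows])
  e_idx <- c(idx[rx$reactant], idx[rx$product[rev_rows]])
  n_ch <- length(k)
  pow <- matrix(0, n_ch, 4, dimnames = list(NULL, c("AA", "O2", "RC", "PGG2")))
  pow[seq_len(n_rx), "AA"]   <- pmax(-rx$dAA, 0)
  pow[seq_len(n_rx), "O2"]   <- pmax(-rx$dO2, 0)
  pow[seq_len(n_rx), "RC"]   <- pmax(-rx$dRC, 0)
  pow[seq_len(n_rx), "PGG2"] <- pmax(-rx$dPGG2, 0)

  S <- matrix(0, length(sn), n_ch, dimnames = list(sn, NULL))
  for (j in seq_len(n_rx)) {
    S[rx$reactant[j], j] <- S[rx$reactant[j], j] - 1
    S[rx$product[j], j]  <- S[rx$product[j], j] + 1
    S["AA", j] <- rx$dAA[j];   S["O2", j] <- rx$dO2[j]
    S["RC", j] <- rx$dRC[j];   S["OC", j] <- rx$dOC[j]
    S["PGG2", j] <- rx$dPGG2[j]; S["PGH2", j] <- rx$dPGH2[j]
    S["SINK", j] <- rx$dSink[j]
  }
  for (m in seq_along(rev_rows)) {      # reverse binding releases AA
    j <- n_rx + m; i <- rev_rows[m]
    S[rx$product[i], j] <- -1
    S[rx$reactant[i], j] <- 1
    S["AA", j] <- 1
  }
  ch_of_rx <- seq_len(n_rx)                       # forward channel per reaction
  rev_of_rx <- rep(NA_integer_, n_rx)
  rev_of_rx[rev_rows] <- n_rx + seq_along(rev_rows)

  # arachidonate-moiety weights per state (free pools + site-bound + sink)
  moiety <- numeric(length(sn))
  names(moiety) <- sn
  cat_sp <- model$species[model$species$kind == "catalytic", ]
  moiety[cat_sp$label] <- .site_moiety(cat_sp$site)
  moiety[c("AA", "PGG2", "PGH2", "SINK")] <- 1

  # at most one consumed metabolite species per channel (O2 enters squared)
  m_idx <- integer(n_ch); m_pow <- integer(n_ch)
  for (m in c("AA", "O2", "RC", "PGG2")) {
    has <- pow[, m] > 0
    m_idx[has] <- idx[[m]]
    m_pow[has] <- pow[has, m]
  }
  list(state_names = sn, idx = idx, k = k, e_idx = unname(e_idx), pow = pow,
       m_idx = m_idx, m_pow = m_pow,
       S = S, n_rx = n_rx, ch_of_rx = ch_of_rx, rev_of_rx = rev_of_rx,
       moiety = moiety, enzyme_cols = model$species$label)
}

# channel rates for a state matrix (rows = times); returns times x channels
.channel_rates <- function(comp, Y) {
  R <- sweep(Y[, comp$e_idx, drop = FALSE], 2, comp$k, "*")
  for (m in c("AA", "O2", "RC", "PGG2")) {
    pw <- comp$pow[, m]
    has <- pw > 0
    if (any(has))                       # the power is uniform per metabolite
      R[, has] <- R[, has] * Y[, comp$idx[[m]]]^max(pw)
  }
  R
}

#' Assemble the mass-action right-hand side of a network model
#'
#' Returns the derivative function of the ODE system in the form expected by
#' \pkg{deSolve}: each reaction contributes
#' \code{rate = k * [enzyme] * prod([consumed metabolites]^stoichiometry)}
#' (oxygen enters squared in the oxygenation step) and the reverse of a
#' binding reaction contributes \code{koff * [complex]}.
#'
#' @param model a \code{pghs_network}.
#' @param o2_clamped hold O2 constant.
#' @return a function \code{(t, y, parms)} returning \code{list(dy)}; the
#'   compiled network is attached as attribute \code{"compiled"} and the
#'   analytic Jacobian function as attribute \code{"jacobian"}.
#' @export
pghs_rhs <- function(model, o2_clamped = FALSE) {
  comp <- .compile_network(model)
  St <- comp$S
  if (o2_clamped) St[comp$idx[["O2"]], ] <- 0
  nz <- which(St != 0, arr.ind = TRUE)
  s_row <- as.integer(nz[, 1]); s_col <- as.integer(nz[, 2])
  s_val <- St[nz]
  k <- comp$k; e_idx <- as.integer(comp$e_idx)
  m_idx <- as.integer(comp$m_idx); m_pow <- as.integer(comp$m_pow)
  n_state <- length(comp$state_names)
  f <- function(t, y, parms) {
    if (length(y) != n_state) stop("dimension mismatch in state vector")
    list(mass_action_rhs(y, k, e_idx, m_idx, m_pow, s_row, s_col, s_val,
                         n_state))
  }
  jac <- function(t, y, parms)
    mass_action_jac(y, k, e_idx, m_idx, m_pow, s_row, s_col, s_val, n_state)
  attr(f, "compiled") <- comp
  attr(f, "jacobian") <- jac
  f
}

#' Simulate a PGHS-1 network model
#'
#' Integrates the mass-action ODE system with the stiff BDF solver
#' (\code{vode}) and records concentration and net reaction-flux time courses
#' on the output grid. Unless overridden via \code{config$init}, the whole enzyme
#' pool starts in the resting state E1.
#'
#' @param model a \code{pghs_network}.
#' @param config a \code{\link{pghs_config}}.
#' @return an object of class \code{"pghs_trajectory"}: list with \code{times}
#'   (s), \code{conc} (times x 35 matrix, uM), \code{flux} (times x reactions
#'   matrix, uM/s, net of the binding back-reactions), \code{config},
#'   \code{model}.
#' @examples
#' \donttest{
#' traj <- pghs_simulate(pghs_network(), pghs_config(RC = 100, t_end = 300))
#' traj
#' }
#' @export
pghs_simulate <- function(model, config = pghs_config()) {
  stopifnot(inherits(model, "pghs_network"), inherits(config, "pghs_config"))
  f <- pghs_rhs(model, o2_clamped = config$o2_clamped)
  comp <- attr(f, "compiled")
  y0 <- numeric(length(comp$state_names))
  names(y0) <- comp$state_names
  if (is.null(config$init)) {
    y0["E1"] <- config$enzyme_total
  } else {
    bad <- setdiff(names(config$init), comp$state_names)
    if (length(bad)) stop("unknown species in init: ", paste(bad, collapse = ", "))
    y0[names(config$init)] <- config$init
  }
  for (m in c("AA", "O2", "RC", "OC", "PGG2", "PGH2")) y0[m] <- config[[m]]

  sol <- deSolve::vode(y = y0, times = config$times, func = f, parms = NULL,
                       jacfunc = attr(f, "jacobian"), jactype = "fullusr",
                       rtol = config$rtol, atol = config$atol,
                       hmax = config$hmax, maxsteps = 500000)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("integrator failure; last successful time %.4g s",
                 max(sol[, "time"], na.rm = TRUE)))
  Y <- unclass(sol)[, -1, drop = FALSE]
  rates <- .channel_rates(comp, Y)
  flux <- rates[, comp$ch_of_rx, drop = FALSE]
  has_rev <- which(!is.na(comp$rev_of_rx))
  if (length(has_rev))
    flux[, has_rev] <- flux[, has_rev] -
      rates[, comp$rev_of_rx[has_rev], drop = FALSE]
  colnames(flux) <- paste0("R", model$reactions$id)
  structure(list(times = sol[, "time"], conc = Y, flux = flux,
                 config = config, model = model),
            class = "pghs_trajectory")
}

#' @export
print.pghs_trajectory <- function(x, ...) {
  n <- nrow(x$conc)
  cat("PGHS-1 trajectory: ", n, " time points over [",
      format(x$times[1]), ", ", format(x$times[n]), "] s\n", sep = "")
  fin <- x$conc[n, c("AA", "PGG2", "PGH2", "RC", "OC", "SINK")]
  cat("final metabolites (uM):\n")
  print(round(fin, 5))
  cons <- pghs_conservation(x)
  cat("max relative conservation drift:", format(max(unlist(cons)), digits = 3), "\n")
  invisible(x)
}

#' @export
plot.pghs_trajectory <- function(x, what = c("AA", "PGG2", "PGH2", "RC"),
                                 log = "x", ...) {
  Y <- x$conc[, what, drop = FALSE]
  t <- x$times
  if (grepl("x", log)) { keep <- t > 0; t <- t[keep]; Y <- Y[keep, , drop = FALSE] }
  graphics::matplot(t, Y, type = "l", lty = 1, log = log,
                    xlab = "time (s)", ylab = "concentration (uM)", ...)
  graphics::legend("topright", legend = what, col = seq_along(what), lty = 1,
                   bty = "n")
  invisible(x)
}

#' @export
as.data.frame.pghs_trajectory <- function(x, ...) {
  data.frame(time = rep(x$times, ncol(x$conc)),
             species = rep(colnames(x$conc), each = length(x$times)),
             concentration = as.vector(x$conc), row.names = NULL)
}

#' Conservation-law drift along a trajectory
#'
#' The network conserves three moieties analytically: total enzyme, RC + OC,
#' and the arachidonate moiety (free AA + site-bound AA/AA*/PGG2* + PGG2 +
#' PGH2 + damage sink). Reports the maximal relative drift of each along the
#' trajectory.
#'
#' @param traj a \code{pghs_trajectory}.
#' @return named list of relative drifts (0 when the initial total is 0).
#' @export
pghs_conservation <- function(traj) {
  comp <- .compile_network(traj$model)
  sp <- traj$model$species$label
  drift <- function(tot) {
    if (abs(tot[1]) < 1e-300) return(max(abs(tot - tot[1])))
    max(abs(tot - tot[1]) / abs(tot[1]))
  }
  enzyme <- rowSums(traj$conc[, sp, drop = FALSE])
  rc_oc <- traj$conc[, "RC"] + traj$conc[, "OC"]
  arachidonate <- as.vector(traj$conc %*% comp$moiety)
  list(enzyme = drift(enzyme), rc_oc = drift(rc_oc),
       arachidonate = drift(arachidonate))
}

#' Net flux time series of selected reactions
#'
#' @param traj a \code{pghs_trajectory}.
#' @param ids reaction selector: internal ids (integer), source reaction
#'   numbers via \code{paper_id = TRUE}, or column names \code{"R<i>"}.
#' @param paper_id interpret numeric \code{ids} as the source numbering.
#' @return matrix (times x reactions) of net fluxes in uM/s.
#' @export
reaction_flux <- function(traj, ids, paper_id = FALSE) {
  rx <- traj$model$reactions
  if (is.character(ids)) {
    cols <- match(ids, colnames(traj$flux))
  } else if (paper_id) {
    cols <- match(as.integer(ids), rx$paper_id)
  } else cols <- match(as.integer(ids), rx$id)
  if (anyNA(cols)) stop("unknown reaction id(s): ",
                        paste(ids[is.na(cols)], collapse = ", "))
  out <- traj$flux[, cols, drop = FALSE]
  colnames(out) <- if (paper_id) paste0("V", ids) else colnames(traj$flux)[cols]
  out
}

#' Maximum-over-time of a flux or concentration series
#' @param x numeric vector or single-column matrix.
#' @return the maximum value.
#' @export
flux_max <- function(x) max(as.numeric(x))

#' Trapezoidal area under a curve
#'
#' @param y values on the grid.
#' @param times strictly increasing time grid (s).
#' @return the trapezoidal integral.
#' @examples
#' auc(rep(2, 5), 0:4)   # 8
#' @export
auc <- function(y, times) {
  y <- as.numeric(y)
  if (length(y) != length(times)) stop("length mismatch between y and times")
  if (is.unsorted(times, strictly = TRUE)) stop("time grid must be increasing")
  sum(diff(times) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Write a trajectory to CSV
#'
#' @param traj a \code{pghs_trajectory}.
#' @param file output path.
#' @param shape \code{"tidy"} (time, species, concentration) or \code{"wide"}
#'   (one column per state).
#' @return the file path, invisibly.
#' @export
write_trajectory <- function(traj, file, shape = c("tidy", "wide")) {
  shape <- match.arg(shape)
  df <- if (shape == "tidy") as.data.frame(traj)
        else data.frame(time = traj$times, traj$conc, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
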