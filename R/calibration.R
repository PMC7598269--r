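# Weighted least-squares calibration of grouped rate constants against
# kinetic time-series datasets, with seeded Latin-hypercube multistart in
# log10 parameter space and profile-likelihood style identifiability scans.

#' Kinetic dataset for calibration
#'
#' Bundles time-series records with the condition blocks they were measured
#' under. Records are (condition_id, observable, time_s, value_uM, weight);
#' observables are \code{PGG2}, \code{PGH2}, \code{AA} or \code{OC}. Each
#' condition block states the total enzyme, initial AA, cosubstrate (RC) and
#' peroxide concentrations and the cosubstrate identity, which selects the
#' peroxidase parameter profile (\code{phenol} -> \code{phenol_pgg2},
#' \code{adrenaline} -> \code{adrenaline_h2o2}). For H2O2-driven peroxidase
#' assays the peroxide pool of the model carries the H2O2 concentration.
#'
#' @param records data.frame with columns \code{condition_id},
#'   \code{observable}, \code{time_s}, \code{value_uM} and optionally
#'   \code{weight} (default 1).
#' @param conditions named list (by condition id) of lists with elements
#'   \code{enzyme_total}, \code{AA}, \code{RC}, \code{H2O2} (default 0),
#'   \code{cosubstrate} (\code{"phenol"} or \code{"adrenaline"}).
#' @return object of class \code{"pghs_dataset"}.
#' @export
pghs_dataset <- function(records, conditions) {
  req <- c("condition_id", "observable", "time_s", "value_uM")
  if (!all(req %in% names(records)))
    stop("records must have columns ", paste(req, collapse = ", "))
  if (is.null(records$weight)) records$weight <- 1
  if (any(records$time_s < 0)) stop("times must be >= 0")
  if (any(records$weight <= 0)) stop("weights must be > 0")
  if (!all(records$observable %in% c("PGG2", "PGH2", "AA", "OC")))
    stop("observables must be among PGG2, PGH2, AA, OC")
  miss <- setdiff(unique(records$condition_id), names(conditions))
  if (length(miss)) stop("conditions missing for: ", paste(miss, collapse = ", "))
  conditions <- lapply(conditions, function(cc) {
    cc$H2O2 <- if (is.null(cc$H2O2)) 0 else cc$H2O2
    cc$cosubstrate <- if (is.null(cc$cosubstrate)) "phenol" else cc$cosubstrate
    cc
  })
  structure(list(records = records, conditions = conditions),
            class = "pghs_dataset")
}

#' @export
print.pghs_dataset <- function(x, ...) {
  cat("PGHS-1 kinetic dataset:", nrow(x$records), "records in",
      length(x$conditions), "condition block(s);",
      "observables:", paste(unique(x$records$observable), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a dataset as CSV + YAML
#'
#' The records go to \code{<stem>.csv} (columns condition_id, observable,
#' time_s, value_uM, weight) and the condition blocks to \code{<stem>.yaml}.
#'
#' @param dataset a \code{pghs_dataset}.
#' @param stem path stem without extension.
#' @return \code{write_dataset}: the stem, invisibly; \code{read_dataset}:
#'   the \code{pghs_dataset}.
#' @export
write_dataset <- function(dataset, stem) {
  utils::write.csv(dataset$records, paste0(stem, ".csv"), row.names = FALSE)
  yaml::write_yaml(dataset$conditions, paste0(stem, ".yaml"))
  invisible(stem)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(stem) {
  pghs_dataset(utils::read.csv(paste0(stem, ".csv"), stringsAsFactors = FALSE),
               yaml::read_yaml(paste0(stem, ".yaml")))
}

.profile_of <- function(cosubstrate) {
  switch(cosubstrate, phenol = "phenol_pgg2", adrenaline = "adrenaline_h2o2",
         stop("unknown cosubstrate: ", cosubstrate))
}

# simulate one condition block and return predictions at the record times.
# The candidate vector is interpreted on the phenol_pgg2 profile; for an
# adrenaline/H2O2 block the peroxidase subset (k5..k8) reverts to that
# profile's defaults unless the constant is in the free mask.
.predict_condition <- function(params, condition, rec, policy,
                               free_names = character()) {
  prof <- .profile_of(condition$cosubstrate)
  pv <- structure(as.numeric(params), names = names(params))
  if (prof == "adrenaline_h2o2") {
    adr <- c(k5 = 0.06, k6 = 0.001, k7 = 0.001, k8 = 0.001)
    repl <- setdiff(names(adr), free_names)
    pv[repl] <- adr[repl]
  }
  p <- as_pghs_parameters(pv, profile = prof)
  net <- pghs_network(p, policy)
  tt <- sort(unique(rec$time_s))
  cfg <- pghs_config(enzyme_total = condition$enzyme_total,
                     AA = condition$AA, RC = condition$RC,
                     PGG2 = 0.01 + condition$H2O2,
                     times = unique(c(0, tt)))
  tr <- pghs_simulate(net, cfg)
  obs_col <- c(PGG2 = "PGG2", PGH2 = "PGH2", AA = "AA", OC = "OC")
  vapply(seq_len(nrow(rec)), function(i) {
    stats::approx(tr$times, tr$conc[, obs_col[[rec$observable[i]]]],
                  xout = rec$time_s[i], rule = 2)$y
  }, numeric(1))
}

# merge free values (natural scale) into a base parameter vector
.merge_params <- function(base, free_names, free_values) {
  p <- structure(as.numeric(base), names = names(base))
  p[free_names] <- free_values
  p
}

#' Weighted sum-of-squares calibration objective
#'
#' For each condition block, simulates the model with the candidate
#' parameters (peroxidase profile chosen per the block's cosubstrate) and
#' accumulates \code{weight x scale x (simulated - observed)^2} over the
#' records; the scale weight is \code{1/max(value)^2} per observable within
#' each dataset, making the objective scale-free across observables of
#' different magnitude. A failed simulation contributes a
#' large finite penalty (flagged via attribute \code{"failed"}) instead of
#' throwing, so optimizers can continue.
#'
#' @param free_values named numeric vector of free-parameter values (natural
#'   scale); may be empty.
#' @param datasets a \code{pghs_dataset} or list of them.
#' @param base_params parameter set supplying all non-free values.
#' @param policy network policy.
#' @return scalar objective.
#' @export
pghs_objective <- function(free_values, datasets,
                           base_params = pghs_parameters(),
                           policy = "composition_complete") {
  if (inherits(datasets, "pghs_dataset")) datasets <- list(datasets)
  p <- .merge_params(base_params, names(free_values), free_values)
  if (any(p < 0)) stop("negative parameter")
  total <- 0; failed <- FALSE
  for (ds in datasets) {
    # scale-free weighting: per observable within the dataset, so that
    # curves of different magnitude (e.g. PGH2 vs PGG2) count equally
    scale_w <- tapply(ds$records$value_uM, ds$records$observable,
                      function(v) 1 / max(v)^2)
    for (cid in unique(ds$records$condition_id)) {
      rec <- ds$records[ds$records$condition_id == cid, , drop = FALSE]
      pred <- tryCatch(
        suppressWarnings(.predict_condition(p, ds$conditions[[cid]], rec,
                                            policy, names(free_values))),
        error = function(e) NULL)
      if (is.null(pred)) { total <- total + 1e8; failed <- TRUE; next }
      total <- total + sum(rec$weight * scale_w[rec$observable] *
                             (pred - rec$value_uM)^2)
    }
  }
  structure(total, failed = failed)
}

# run fn with a locally seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  fn()
}

#' Fit free parameters to kinetic datasets
#'
#' Multistart weighted least squares: \code{n_starts} Latin-hypercube points
#' are drawn in log10 space within the bounds (default +/- 3 decades around
#' the defaults), all are scored, and the \code{refine} best are polished
#' with a derivative-free Nelder-Mead search in log10 space (golden-section
#' for a single free parameter). The whole procedure is deterministic for a
#' fixed seed.
#'
#' @param datasets a \code{pghs_dataset} or list of them.
#' @param free character vector of free parameter names (the remaining
#'   constants stay at \code{base_params}; grouped reactions share these
#'   constants by construction of the network templates).
#' @param base_params parameter set of fixed values and fallback defaults.
#' @param lower,upper optional named bounds (natural scale).
#' @param n_starts number of Latin-hypercube starts.
#' @param refine how many of the best-scoring starts to polish locally.
#' @param seed RNG seed for the start design.
#' @param policy network policy.
#' @return object of class \code{"pghs_fit"}: estimates, objective, start
#'   table, bounds-hit flags, per-record residuals, convergence info.
#' @export
pghs_fit <- function(datasets, free, base_params = pghs_parameters(),
                     lower = NULL, upper = NULL, n_starts = 16, refine = 4,
                     seed = 1, policy = "composition_complete") {
  stopifnot(length(free) >= 1, all(free %in% names(base_params)))
  if (inherits(datasets, "pghs_dataset")) datasets <- list(datasets)
  defaults <- structure(as.numeric(base_params), names = names(base_params))
  lo <- log10(defaults[free]) - 3
  hi <- log10(defaults[free]) + 3
  if (!is.null(lower)) lo[names(lower)] <- log10(lower)
  if (!is.null(upper)) hi[names(upper)] <- log10(upper)

  obj_log <- function(theta) {
    v <- 10^theta; names(v) <- free
    as.numeric(pghs_objective(v, datasets, base_params, policy))
  }
  starts <- .with_seed(seed, function() lhs::randomLHS(n_starts, length(free)))
  starts <- sweep(sweep(starts, 2, hi - lo, "*"), 2, lo, "+")
  colnames(starts) <- free
  start_obj <- apply(starts, 1, obj_log)

  refine <- min(refine, n_starts)
  best_rows <- order(start_obj)[seq_len(refine)]
  clamp <- function(th) pmin(pmax(th, lo), hi)
  obj_box <- function(th) {
    if (any(th < lo - 1e-9) || any(th > hi + 1e-9)) return(1e10)
    obj_log(clamp(th))
  }
  # derivative-free local polish: the objective is cheap only in relative
  # terms and piecewise-rough near integrator-failure penalties, where
  # gradient-based searches stall
  fits <- lapply(best_rows, function(i) {
    if (length(free) == 1) {
      res <- stats::optimize(function(t1) obj_log(t1), c(lo, hi), tol = 1e-6)
      list(par = structure(res$minimum, names = free),
           objective = res$objective, convergence = 0L, message = NULL)
    } else {
      res <- stats::optim(starts[i, ], obj_box, method = "Nelder-Mead",
                          control = list(maxit = 250, reltol = 1e-9))
      list(par = clamp(res$par), objective = res$value,
           convergence = res$convergence, message = res$message)
    }
  })
  objectives <- vapply(fits, function(f) f$objective, numeric(1))
  best <- fits[[which.min(objectives)]]
  theta <- best$par
  est <- 10^theta; names(est) <- free
  bounds_hit <- (theta <= lo + 1e-9) | (theta >= hi - 1e-9)

  p_hat <- .merge_params(base_params, free, est)
  resid <- lapply(datasets, function(ds) {
    do.call(rbind, lapply(unique(ds$records$condition_id), function(cid) {
      rec <- ds$records[ds$records$condition_id == cid, , drop = FALSE]
      rec$predicted <- .predict_condition(p_hat, ds$conditions[[cid]], rec,
                                          policy, free)
      rec$residual <- rec$predicted - rec$value_uM
      rec
    }))
  })
  structure(list(estimates = est, objective = best$objective,
                 bounds_hit = bounds_hit, free = free,
                 base_params = base_params, policy = policy,
                 starts = data.frame(starts, objective = start_obj),
                 refined_objectives = objectives,
                 convergence = best$convergence, message = best$message,
                 residuals = resid, datasets = datasets, seed = seed),
            class = "pghs_fit")
}

#' @export
print.pghs_fit <- function(x, ...) {
  cat("PGHS-1 calibration fit (", length(x$free), " free parameter(s), ",
      nrow(x$starts), " starts, seed ", x$seed, ")\n", sep = "")
  cat("objective:", format(x$objective, digits = 6), "\n")
  est <- x$estimates
  flag <- ifelse(x$bounds_hit, " [bound]", "")
  for (i in seq_along(est))
    cat(sprintf("  %-5s %.6g%s\n", names(est)[i], est[i], flag[i]))
  invisible(x)
}

#' @export
coef.pghs_fit <- function(object, ...) object$estimates

#' @export
residuals.pghs_fit <- function(object, ...)
  do.call(rbind, object$residuals)

#' @export
summary.pghs_fit <- function(object, ...) {
  print(object)
  r <- residuals(object)
  cat("residual summary (uM):\n")
  print(summary(r$residual))
  invisible(object)
}

#' Objective profile of one parameter
#'
#' Fixes the chosen parameter at each grid value and re-minimises the
#' objective over the remaining free parameters (started from the supplied
#' estimates). A flat profile flags a parameter the data do not constrain.
#'
#' @param datasets a \code{pghs_dataset} or list of them.
#' @param free free-parameter names (must contain \code{parameter}).
#' @param parameter the parameter to profile.
#' @param grid natural-scale values to profile over.
#' @param start named start values for the free parameters (e.g.
#'   \code{coef(fit)}); defaults to \code{base_params[free]}.
#' @inheritParams pghs_fit
#' @return data.frame with columns \code{value}, \code{objective}.
#' @export
profile_objective <- function(datasets, free, parameter, grid,
                              base_params = pghs_parameters(), start = NULL,
                              policy = "composition_complete") {
  if (!parameter %in% free) stop("parameter must be in the free mask")
  others <- setdiff(free, parameter)
  defaults <- structure(as.numeric(base_params), names = names(base_params))
  if (is.null(start)) start <- defaults[free]
  out <- data.frame(value = grid, objective = NA_real_)
  for (i in seq_along(grid)) {
    fixed <- structure(grid[i], names = parameter)
    if (!length(others)) {
      out$objective[i] <- as.numeric(
        pghs_objective(fixed, datasets, base_params, policy))
      next
    }
    lo <- log10(defaults[others]) - 3; hi <- log10(defaults[others]) + 3
    obj <- function(theta) {
      v <- c(10^theta, fixed)
      names(v) <- c(others, parameter)
      as.numeric(pghs_objective(v, datasets, base_params, policy))
    }
    fit <- stats::nlminb(log10(start[others]), obj, lower = lo, upper = hi,
                         control = list(iter.max = 100, eval.max = 200))
    out$objective[i] <- fit$objective
  }
  out
}
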