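# Morris elementary-effects global sensitivity analysis.
#
# One-at-a-time trajectory design on a p-level grid in the unit hypercube,
# mapped to log-uniform parameter ranges; per-parameter mean mu and standard
# deviation sigma of the elementary effects, ranked by sqrt(mu^2 + sigma^2).

#' Morris sampling plan
#'
#' @param parameters names of the parameters screened.
#' @param r number of trajectories.
#' @param levels number of grid levels p (must be even); the jump is
#'   \code{delta = p / (2 (p - 1))}.
#' @param seed RNG seed for the design.
#' @param ranges 2 x k matrix of lower/upper parameter bounds (natural
#'   scale), or \code{NULL} for the default log-uniform x/÷ \code{span}
#'   decades around \code{defaults}.
#' @param defaults named defaults the ranges are centred on.
#' @param span half-width of the default range in decades (1 = x/÷ 10).
#' @return object of class \code{"morris_plan"}.
#' @export
morris_plan <- function(parameters = names(pghs_parameters()), r = 100,
                        levels = 4, seed = 1, ranges = NULL,
                        defaults = pghs_parameters(), span = 1) {
  if (levels %% 2 != 0 || levels < 2) stop("levels must be even and >= 2")
  if (r < 2) stop("need at least 2 trajectories")
  if (is.null(ranges)) {
    d <- structure(as.numeric(defaults), names = names(defaults))[parameters]
    if (anyNA(d)) stop("no default value for some parameters")
    if (any(d <= 0))
      stop("log-uniform default ranges need positive defaults; supply ranges")
    ranges <- rbind(lower = d / 10^span, upper = d * 10^span)
  }
  colnames(ranges) <- parameters
  if (any(!is.finite(ranges)) || any(ranges <= 0))
    stop("ranges must be finite and positive")
  structure(list(parameters = parameters, r = r, levels = levels, seed = seed,
                 ranges = ranges),
            class = "morris_plan")
}

#' Sample a Morris one-at-a-time design
#'
#' Generates \code{r} trajectories of \code{k + 1} points each on the
#' p-level grid \code{\{0, 1/(p-1), ..., 1\}} of the unit hypercube (base
#' points restricted to levels <= 1 - delta), each consecutive pair differing
#' in exactly one coordinate by +/- delta, then maps the unit coordinates
#' log-uniformly onto the parameter ranges.
#'
#' @param plan a \code{\link{morris_plan}}.
#' @return matrix of natural-scale parameter values with \code{r (k+1)}
#'   rows; attributes \code{unit} (the unit-hypercube design) and
#'   \code{steps} (data.frame: \code{before}, \code{after} row indices,
#'   \code{param}, signed unit \code{delta}).
#' @export
morris_sample <- function(plan) {
  k <- length(plan$parameters); p <- plan$levels; r <- plan$r
  delta <- p / (2 * (p - 1))
  base_levels <- seq(0, 1 - delta, by = 1 / (p - 1))
  unit <- matrix(NA_real_, r * (k + 1), k)
  steps <- vector("list", r)
  .with_seed(plan$seed, function() {
    for (tr in seq_len(r)) {
      x <- base_levels[sample.int(length(base_levels), k, replace = TRUE)]
      dirs <- sample(c(-1, 1), k, replace = TRUE)
      # start at the end of the box that allows the chosen step
      x <- ifelse(dirs > 0, x, x + delta)
      ord <- sample.int(k)
      rows <- (tr - 1) * (k + 1) + seq_len(k + 1)
      unit[rows[1], ] <<- x
      for (j in seq_len(k)) {
        x[ord[j]] <- x[ord[j]] + dirs[ord[j]] * delta
        unit[rows[j + 1], ] <<- x
      }
      steps[[tr]] <<- data.frame(before = rows[seq_len(k)],
                                 after = rows[seq_len(k) + 1],
                                 param = plan$parameters[ord],
                                 delta = dirs[ord] * delta)
    }
  })
  lo <- log10(plan$ranges["lower", ]); hi <- log10(plan$ranges["upper", ])
  design <- 10^sweep(sweep(unit, 2, hi - lo, "*"), 2, lo, "+")
  colnames(design) <- plan$parameters
  structure(design, unit = unit, steps = do.call(rbind, steps), plan = plan)
}

#' Elementary effects from a design and its outputs
#'
#' For every one-at-a-time step, \code{EE = (y_after - y_before) / delta}
#' with the signed unit-space jump \code{delta}; per parameter, \code{mu} is
#' the mean and \code{sigma} the standard deviation of its elementary
#' effects. Steps with non-finite outputs are dropped and counted.
#'
#' @param design a design from \code{\link{morris_sample}}.
#' @param y numeric outputs aligned with the design rows.
#' @return object of class \code{"morris_result"}: data.frame with columns
#'   \code{parameter}, \code{mu}, \code{sigma}, \code{ranking}, \code{n_ee},
#'   \code{n_dropped}, sorted by decreasing ranking.
#' @export
elementary_effects <- function(design, y) {
  steps <- attr(design, "steps")
  if (is.null(steps)) stop("design lacks Morris step annotations")
  if (length(y) != nrow(design)) stop("outputs not aligned with design rows")
  ee <- (y[steps$after] - y[steps$before]) / steps$delta
  params <- colnames(design)
  out <- do.call(rbind, lapply(params, function(pn) {
    e <- ee[steps$param == pn]
    keep <- is.finite(e)
    data.frame(parameter = pn, mu = mean(e[keep]),
               sigma = stats::sd(e[keep]),
               n_ee = sum(keep), n_dropped = sum(!keep))
  }))
  out$ranking <- sqrt(out$mu^2 + out$sigma^2)
  out <- out[order(-out$ranking), c("parameter", "mu", "sigma", "ranking",
                                    "n_ee", "n_dropped")]
  rownames(out) <- NULL
  structure(out, class = c("morris_result", "data.frame"))
}

#' Ranked parameter list of a Morris result
#'
#' The ranking statistic is \code{sqrt(mu^2 + sigma^2)} per parameter,
#' which dominates both the mean effect and the interaction/nonlinearity
#' spread componentwise.
#'
#' @param result a \code{morris_result}.
#' @return the result ordered by decreasing ranking.
#' @export
morris_ranking <- function(result) {
  stopifnot(inherits(result, "morris_result"))
  result[order(-result$ranking), ]
}

#' Morris screening of the PGHS-1 model
#'
#' Runs the full elementary-effects analysis of the kinetic model: samples
#' the design, simulates the model at every design point and evaluates the
#' output functional (by default the area under the PGH2 time course under
#' the stated configuration), then aggregates the effects.
#'
#' @param plan a \code{\link{morris_plan}} over model parameter names.
#' @param config simulation configuration for the output functional.
#' @param output function(trajectory) -> scalar; default AUC of PGH2.
#' @param policy network policy.
#' @param progress print a dot every 100 evaluations.
#' @return a \code{morris_result} (see \code{\link{elementary_effects}})
#'   with the design attached as attribute \code{"design"}.
#' @export
pghs_morris <- function(plan = morris_plan(),
                        config = pghs_config(enzyme_total = 0.035, AA = 80,
                                             RC = 100, t_end = 1200),
                        output = function(tr) auc(tr$conc[, "PGH2"], tr$times),
                        policy = "composition_complete", progress = FALSE) {
  design <- morris_sample(plan)
  y <- numeric(nrow(design))
  for (i in seq_len(nrow(design))) {
    p <- tryCatch(as_pghs_parameters(design[i, ]), error = function(e) NULL)
    y[i] <- if (is.null(p)) NA_real_ else
      tryCatch(output(pghs_simulate(pghs_network(p, policy), config)),
               error = function(e) NA_real_)
    if (progress && i %% 100 == 0) cat(".")
  }
  if (progress) cat("\n")
  res <- elementary_effects(design, y)
  attr(res, "design") <- design
  res
}

#' @export
print.morris_result <- function(x, ...) {
  cat("Morris elementary-effects screening (", sum(x$n_ee[1]), " EEs/parameter)\n",
      sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write a Morris result to CSV (parameter, mu, sigma, ranking)
#' @param result a \code{morris_result}.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_morris <- function(result, file) {
  utils::write.csv(result[, c("parameter", "mu", "sigma", "ranking")], file,
                   row.names = FALSE)
  invisible(file)
}
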