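# ODE assembly, integration, conservation accounting and flux bookkeeping.

test_that("assembled RHS matches a hand-coded oracle on the core subnetwork", {
  # reduced branched-chain loop: initiation (11), electron transfer (13),
  # AA binding (1), H abstraction (2), oxygenation (3), release (4)
  sub <- pghs_subnetwork(default_network(), c(11, 13, 1, 2, 3, 4))
  f <- pghs_rhs(sub)
  comp <- attr(f, "compiled")
  sn <- comp$state_names
  idx <- function(s) which(sn == s)
  oracle <- function(y) {
    v11 <- 7.1 * y[idx("E1")] * y[idx("PGG2")]
    v13 <- 310 * y[idx("E2")]
    v1  <- 690 * y[idx("E5")] * y[idx("AA")] - 69 * y[idx("E9")]
    v2  <- 2690 * y[idx("E9")]
    v3  <- 173 * y[idx("E13")] * y[idx("O2")]^2
    v4  <- 13 * y[idx("E8")]
    dy <- numeric(length(sn))
    dy[idx("E1")]  <- -v11
    dy[idx("E2")]  <- v11 - v13
    dy[idx("E5")]  <- v13 - v1 + v4
    dy[idx("E9")]  <- v1 - v2
    dy[idx("E13")] <- v2 - v3
    dy[idx("E8")]  <- v3 - v4
    dy[idx("AA")]  <- -v1
    dy[idx("O2")]  <- -2 * v3
    dy[idx("PGG2")] <- -v11 + v4
    dy[idx("PGH2")] <- v11
    dy
  }
  set.seed(101)
  for (i in 1:100) {
    y <- stats::runif(length(sn), 0, 2)
    expect_equal(f(0, y, NULL)[[1]], oracle(y), tolerance = 1e-13)
  }
  # analytic Jacobian agrees with a central finite difference
  y <- stats::runif(length(sn), 0, 2)
  J <- attr(f, "jacobian")(0, y, NULL)
  h <- 1e-6
  for (j in sample(seq_along(sn), 8)) {
    yp <- y; ym <- y; yp[j] <- yp[j] + h; ym[j] <- ym[j] - h
    expect_equal(J[, j], (f(0, yp, NULL)[[1]] - f(0, ym, NULL)[[1]]) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("zero enzyme leaves metabolites constant; rates are linear in k", {
  net <- default_network()
  tr0 <- pghs_simulate(net, pghs_config(enzyme_total = 0, t_end = 100))
  for (m in c("AA", "O2", "RC", "OC", "PGG2", "PGH2"))
    expect_equal(max(abs(tr0$conc[, m] - tr0$conc[1, m])), 0)
  # doubling the peroxidase constant doubles every G6 flux at the (identical)
  # initial state
  net2 <- pghs_network(pghs_parameters(k7 = 2 * 7.1))
  cfg <- pghs_config(t_end = 10)
  f1 <- pghs_simulate(net, cfg)$flux[1, net$reactions$template == "G6"]
  f2 <- pghs_simulate(net2, cfg)$flux[1, net2$reactions$template == "G6"]
  expect_equal(unname(f2), unname(2 * f1), tolerance = 1e-12)
})

test_that("conservation laws hold to 1e-6 and concentrations stay non-negative", {
  for (tr in list(cached_traj(80, 100), cached_traj(80, 1000),
                  cached_traj(20, 20, t_end = 300))) {
    cons <- pghs_conservation(tr)
    expect_lt(cons$enzyme, 1e-6)
    expect_lt(cons$rc_oc, 1e-6)
    expect_lt(cons$arachidonate, 1e-6)
    expect_gt(min(tr$conc), -1e-8)
  }
})

test_that("default parameters drive full self-inactivation; disabling
           inactivation sustains turnover", {
  tr <- cached_traj(80, 100)
  n <- nrow(tr$conc)
  cat_sp <- default_network()$species$label[default_network()$species$kind ==
                                              "catalytic"]
  expect_lt(sum(tr$conc[n, cat_sp]), 1e-6 * 0.035)
  expect_gt(tr$conc[n, "FIE"] + sum(tr$conc[n, c("D1", "D2", "D3")]),
            0.035 * 0.999)
  # PGH2 approaches a plateau: negligible late production
  late <- tr$times > 0.9 * max(tr$times)
  expect_lt(diff(range(tr$conc[late, "PGH2"])), 0.01 * tr$conc[n, "PGH2"])
  # without self-inactivation and with ample substrates the system keeps
  # producing PGH2 to the end of the run
  net0 <- pghs_network(pghs_parameters(kin = 0, kin1 = 0, kin2 = 0))
  tr0 <- pghs_simulate(net0, pghs_config(AA = 200, RC = 2000, t_end = 600))
  v_late <- diff(tr0$conc[, "PGH2"]) / diff(tr0$times)
  expect_gt(utils::tail(v_late, 1), 1e-5)
  # inactivation-route fluxes vanish identically when the constants are zero
  s_idx <- which(startsWith(net0$reactions$template, "S"))
  expect_true(all(tr0$flux[, s_idx] == 0))
})

test_that("halving solver tolerances leaves the endpoint unchanged to 1e-4", {
  net <- default_network()
  cfg1 <- pghs_config(AA = 80, RC = 300, t_end = 300)
  cfg2 <- pghs_config(AA = 80, RC = 300, t_end = 300,
                      rtol = 0.5e-8, atol = 0.5e-10)
  p1 <- pghs_simulate(net, cfg1)$conc[, "PGH2"]
  p2 <- pghs_simulate(net, cfg2)$conc[, "PGH2"]
  n <- length(p1)
  expect_equal(p1[n], p2[n], tolerance = 1e-4)
})

test_that("flux accounting: peroxidase integral equals PGH2 produced and
           AA binds overwhelmingly to the Tyr-radical state", {
  tr <- cached_traj(80, 100)
  net <- default_network()
  g6 <- rowSums(tr$flux[, net$reactions$template == "G6", drop = FALSE])
  produced <- auc(g6, tr$times)
  n <- nrow(tr$conc)
  expect_equal(produced, tr$conc[n, "PGH2"] - tr$conc[1, "PGH2"],
               tolerance = 0.01, ignore_attr = TRUE)
  # binding to the activated (Tyr385*) state dominates binding to the
  # resting state by far more than an order of magnitude on the reporting
  # grid (the t = 0 mixing discontinuity is excluded)
  v1 <- reaction_flux(tr, 1, paper_id = TRUE)[-1, ]
  v31 <- reaction_flux(tr, 31, paper_id = TRUE)[-1, ]
  expect_gt(max(v1), 10 * max(v31))
  expect_error(reaction_flux(tr, 999, paper_id = TRUE), "unknown reaction")
})

test_that("simulation rejects invalid configurations", {
  expect_error(pghs_config(AA = -1), ">= 0")
  expect_error(pghs_config(times = c(0, 2, 1)), "increasing")
  net <- default_network()
  expect_error(pghs_simulate(net, pghs_config(init = c(EX = 1))),
               "unknown species")
})
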