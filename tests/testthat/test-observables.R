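# Derived observables: oxygen consumption, dose-response, apparent Km,
# Eadie-Scatchard, activation threshold, consumption stoichiometry, AUC.

test_that("oxygen consumption rate obeys the 2:1 oxygenation stoichiometry", {
  tr <- cached_traj(80, 300, t_end = 300)
  v <- oxygen_consumption_rate(tr)
  # fluxes inherit only solver-level undershoot (sub-nM state noise is
  # amplified by the fast oxygenation constant)
  expect_gt(min(v), -1e-6)
  # single activity burst: rises to one maximum then decays towards zero
  imax <- which.max(v)
  expect_gt(imax, 1)
  expect_lt(utils::tail(v, 1), 0.01 * max(v))
  # V_O2 is the oxygen consumption rate: its time integral equals the
  # oxygen consumed (each oxygenation event consumes 2 O2 and contributes
  # twice its flux to V_O2, so the factors cancel exactly)
  o2_used <- tr$conc[1, "O2"] - tr$conc[nrow(tr$conc), "O2"]
  expect_equal(auc(v, tr$times), o2_used, tolerance = 0.005,
               ignore_attr = TRUE)
  # zero-enzyme trajectory has identically zero V_O2
  tr0 <- pghs_simulate(default_network(), pghs_config(enzyme_total = 0,
                                                      t_end = 10))
  expect_true(all(oxygen_consumption_rate(tr0) == 0))
})

test_that("apparent-Km extraction is exact on a closed-form Michaelis curve", {
  aa <- c(seq(0.2, 10, by = 0.2), 20, 50, 150, 300, 600)
  toy <- structure(data.frame(AA = aa, rate = 10 * aa / (3 + aa),
                              failed = FALSE),
                   class = c("pghs_dose_response", "data.frame"))
  km <- apparent_km(toy)
  expect_true(km$plateau)
  expect_equal(km$Vmax, 10, tolerance = 0.01)
  expect_equal(km$Km, 3, tolerance = 0.02)
  # its Eadie-Scatchard transform is a straight line of slope -1/Km
  es <- eadie_scatchard(toy, enzyme_total = 1)
  fitline <- stats::lm(v_aa_e ~ v_e, data = es)
  expect_equal(unname(coef(fitline)[2]), -1 / 3, tolerance = 1e-6)
  expect_lt(max(abs(stats::residuals(fitline))), 1e-9)
  expect_lt(attr(es, "deviation"), 1e-9)
  expect_false(attr(es, "concave"))
  # a curve still rising at the end is flagged as plateau-free
  rising <- structure(data.frame(AA = c(1, 2, 4, 8), rate = c(1, 2, 4, 8),
                                 failed = FALSE),
                      class = c("pghs_dose_response", "data.frame"))
  expect_false(apparent_km(rising)$plateau)
  expect_true(is.na(apparent_km(rising)$Km))
})

test_that("cosubstrate raises the apparent Km and bends the dose-response
           sigmoidal (positive cooperativity)", {
  net <- default_network()
  aa_grid <- c(0.2, 0.5, 1, 2, 4, 8, 16, 40, 80)
  cfg <- pghs_config(t_end = 100)
  low <- dose_response(net, aa_grid, rc = 100, config = cfg)
  high <- dose_response(net, aa_grid, rc = 5000, config = cfg)
  expect_true(all(!low$failed) && all(!high$failed))
  expect_true(all(low$rate >= 0))
  # AA = 0 gives zero rate
  z <- dose_response(net, c(0, 1), rc = 100, config = cfg)
  expect_equal(z$rate[1], 0)
  # monotone non-decreasing dose response at 1000 uM cosubstrate
  mid <- dose_response(net, aa_grid, rc = 1000, config = cfg)
  expect_true(all(diff(mid$rate) > -1e-9))
  # high cosubstrate: lower maximal rate, right-shifted half-saturation
  km_low <- apparent_km(low); km_high <- apparent_km(high)
  expect_lt(km_high$Vmax, km_low$Vmax)
  expect_gt(km_high$Km, km_low$Km)
  # the apparent Km sits in the experimentally reported order of magnitude
  expect_gt(km_low$Km, 0.05); expect_lt(km_low$Km, 20)
  # Eadie-Scatchard of the high-RC curve departs strongly from a line and
  # is downward-concave with the cooperative hook at the sigmoid foot,
  # unlike the Michaelis toy above
  es <- eadie_scatchard(high, enzyme_total = 0.035)
  expect_true(attr(es, "concave"))
  expect_gt(attr(es, "deviation"), 0.1)
  imax <- which.max(es$v_aa_e)
  expect_gt(imax, 1); expect_lt(imax, nrow(es))
})

test_that("activation threshold rises with cosubstrate and respects edge
           cases", {
  net <- default_network()
  th <- activation_threshold(net, rc_grid = c(100, 1000, 5000),
                             criterion = 0.02, t_eval = 300)
  expect_true(all(th$threshold_AA > 0))
  expect_true(all(diff(th$threshold_AA) > -1e-9))   # monotone non-decreasing
  expect_false(any(th$at_boundary))
  # criterion 0 is met everywhere: threshold collapses to the search bound
  th0 <- activation_threshold(net, rc_grid = 100, criterion = 0,
                              t_eval = 60)
  expect_true(th0$at_boundary[1])
  expect_equal(th0$threshold_AA[1], 1e-3)
  # bisection is bracket-independent to within its 1% tolerance
  th_a <- activation_threshold(net, 1000, aa_range = c(1e-3, 50))
  th_b <- activation_threshold(net, 1000, aa_range = c(1e-2, 20))
  expect_equal(th_a$threshold_AA, th_b$threshold_AA, tolerance = 0.03)
})

test_that("consumption ratio is bounded by peroxidase stoichiometry and
           vanishes without cosubstrate oxidation", {
  tr <- cached_traj(80, 100, t_end = 40)
  r <- consumption_ratio(tr, 30)
  expect_gt(r, 0); expect_lte(r, 2)   # two RC per full PGG2 -> PGH2 conversion
  # with every RC-oxidising constant zeroed the ratio is exactly 0
  net_norc <- pghs_network(pghs_parameters(k5 = 0, k6 = 0, k8 = 0, k10 = 0))
  tr0 <- pghs_simulate(net_norc, pghs_config(AA = 80, RC = 100, t_end = 40))
  expect_equal(consumption_ratio(tr0, 30), 0)
  expect_error(consumption_ratio(tr, 1e6), "span")
  # undefined when AA is not consumed
  tr_no_enz <- pghs_simulate(default_network(),
                             pghs_config(enzyme_total = 0, t_end = 40))
  expect_warning(r0 <- consumption_ratio(tr_no_enz, 30), "undefined")
  expect_true(is.na(r0))
})

test_that("flux table responds to inactivation as expected", {
  net <- default_network()
  cfg <- pghs_config(t_end = 120)
  ft <- flux_table(net, c(100, 1000), config = cfg)
  expect_equal(dim(ft), c(2, 10))
  # removing self-inactivation can only increase the maximal fluxes
  net0 <- pghs_network(pghs_parameters(kin = 0, kin1 = 0, kin2 = 0))
  ft0 <- flux_table(net0, c(100, 1000), config = cfg)
  expect_true(all(as.matrix(ft0[, -1]) >= as.matrix(ft[, -1]) * 0.999))
  expect_error(flux_table(net, c(-10)), "positive")
})

test_that("trapezoidal AUC matches closed forms and refines stably", {
  expect_equal(auc(rep(3, 7), seq(0, 12, by = 2)), 36)
  tt <- seq(0, 2, length.out = 101)
  expect_equal(auc(tt^2, tt), 8 / 3, tolerance = 1e-3)
  fine <- seq(0, 2, length.out = 1001)
  expect_equal(auc(fine^2, fine), 8 / 3, tolerance = 1e-5)
  expect_error(auc(1:3, 1:4), "length mismatch")
  expect_error(auc(1:3, c(1, 3, 2)), "increasing")
})
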