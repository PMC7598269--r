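# shared fixtures: memoised default network and trajectories so repeated
# tests do not re-simulate identical conditions

.cache <- new.env(parent = emptyenv())

default_network <- function() {
  if (is.null(.cache$net)) .cache$net <- pghs_network()
  .cache$net
}

# trajectory cache keyed by condition
cached_traj <- function(AA, RC, t_end = 1200, enzyme_total = 0.035) {
  key <- paste("tr", AA, RC, t_end, enzyme_total, sep = "_")
  if (is.null(.cache[[key]]))
    .cache[[key]] <- pghs_simulate(
      default_network(),
      pghs_config(enzyme_total = enzyme_total, AA = AA, RC = RC,
                  t_end = t_end))
  .cache[[key]]
}

table2_defaults <- c(
  k1 = 690, Kd1 = 0.1, k2 = 2690, k3 = 173, k4 = 13, k5 = 0.18, k6 = 0.58,
  k7 = 7.1, k8 = 0.001, k9 = 310, k10 = 0.1, k11 = 1.1, k12 = 690,
  Kd12 = 0.6, k13 = 18.8, kin = 0.72, kin1 = 0.6, kin2 = 2.5)

# recovery-harness fixture: PG-kinetics-type conditions spanning low RC
# (where the COX-inactivation constant has leverage distinct from the fixed
# Intermediate-II channel), 15 log-spaced sampling times over 1-600 s
recovery_fixture <- function(noise_sd = 0.05, seed = 42) {
  conds <- stats::setNames(
    lapply(c(10, 100, 1000), function(rc)
      list(enzyme_total = 0.035, AA = 80, RC = rc, H2O2 = 0,
           cosubstrate = "phenol")),
    paste0("phenol_", c(10, 100, 1000)))
  generate_fixtures(
    fixture_spec("PG_KINETICS",
                 times = 10^seq(0, log10(600), length.out = 15),
                 noise_sd = noise_sd, seed = seed, conditions = conds))
}
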