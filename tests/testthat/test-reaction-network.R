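# Microstate enumeration and template-driven reaction instantiation.

test_that("species enumeration is exhaustive, duplicate-free and canonical", {
  sp <- pghs_species()
  expect_equal(nrow(sp), 28)
  expect_equal(sum(sp$kind == "catalytic"), 24)
  expect_equal(sum(sp$kind == "cox_dead"), 3)
  expect_equal(sum(sp$kind == "fie"), 1)
  expect_false(anyDuplicated(sp$label) > 0)
  cat24 <- sp[sp$kind == "catalytic", ]
  # every heme x tyr x site composition appears exactly once
  expect_false(anyDuplicated(cat24[, c("heme", "tyr", "site")]) > 0)
  # anchored label assignments: resting state and the Tyr-radical AA complex
  expect_equal(sp["E1", c("heme", "tyr", "site")],
               data.frame(heme = "FeIII_PP", tyr = "Tyr", site = "empty",
                          row.names = "E1"))
  expect_equal(sp["E9", c("heme", "tyr", "site")],
               data.frame(heme = "FeIV_PP", tyr = "TyrRad", site = "AA",
                          row.names = "E9"))
  # half of the catalytic set carries the tyrosyl radical
  expect_equal(sum(cat24$tyr == "TyrRad"), 12)
  # one COX-dead species per heme state
  expect_setequal(sp$heme[sp$kind == "cox_dead"],
                  c("FeIII_PP", "FeIV_PPrad", "FeIV_PP"))
})

test_that("rate constants and binding reversibility follow the parameter set", {
  net <- default_network()
  rx <- net$reactions
  # AA binding to the Tyr-radical resting-activity state: kon 690, Kd 0.1
  r1 <- rx[which(rx$paper_id == 1), ]
  expect_equal(r1$reactant, "E5"); expect_equal(r1$product, "E9")
  expect_equal(r1$rate, 690)
  expect_true(r1$reversible)
  expect_equal(r1$rev_rate, 69)   # koff = kon * Kd
  # ground-Tyr binding carries the weaker affinity
  r31 <- rx[which(rx$paper_id == 31), ]
  expect_equal(r31$reactant, "E1")
  expect_equal(r31$rev_rate, 690 * 0.6)
  # intramolecular electron transfer: fast with an empty COX site,
  # slow when the site is occupied
  r13 <- rx[which(rx$paper_id == 13), ]
  expect_equal(c(r13$reactant, r13$product), c("E2", "E5"))
  expect_equal(r13$rate, 310)
  r18 <- rx[which(rx$paper_id == 18), ]
  expect_equal(c(r18$reactant, r18$product), c("E10", "E9"))
  expect_equal(r18$rate, 1.1)
  # only binding templates are reversible
  expect_setequal(unique(rx$template[rx$reversible]), c("G1", "G2"))
})

test_that("switching inactivation off removes all routes into dead species", {
  net0 <- pghs_network(pghs_parameters(kin = 0, kin1 = 0, kin2 = 0))
  dead <- c("D1", "D2", "D3", "FIE")
  # no active route leads from the catalytic pool into a dead species
  # (the peroxidase-only cycle among the COX-dead species remains but is
  # unreachable)
  into_dead <- net0$reactions$product %in% dead &
    !(net0$reactions$reactant %in% dead)
  expect_true(all(net0$reactions$rate[into_dead] == 0))
  # with defaults, FIE is produced by every PP*+-bearing species
  net <- default_network()
  s1 <- net$reactions[net$reactions$template == "S1", ]
  expect_true(all(s1$product == "FIE"))
  expect_setequal(s1$reactant,
                  c("E2", "E7", "E10", "E11", "E19", "E21", "E22", "E23", "D2"))
  # the Intermediate-II-derived inactivation route fires from exactly four states
  s2 <- net$reactions[net$reactions$template == "S2", ]
  expect_setequal(s2$reactant, c("E5", "E9", "E15", "E20"))
})

test_that("reaction counts are frozen and the restricted policy is a subset", {
  net <- default_network()
  # regression pin from exhaustive template application over all 28 species
  expect_equal(nrow(net$reactions), 91)
  counts <- table(net$reactions$template)
  expect_equal(as.integer(counts[c("G1", "G2", "G3", "G4", "G5", "G6", "G7",
                                   "G8", "G9", "G10", "G11", "S1", "S2",
                                   "S3")]),
               c(3, 3, 3, 6, 3, 9, 9, 9, 12, 4, 2, 9, 4, 15))
  pe <- pghs_network(policy = "paper_enumerated")
  expect_equal(nrow(pe$reactions), 56)
  key <- function(r) paste(r$template, r$reactant, r$product)
  expect_true(all(key(pe$reactions) %in% key(net$reactions)))
  # enzyme moiety: every reaction maps one enzyme species to one
  expect_true(all(net$reactions$reactant %in% net$species$label))
  expect_true(all(net$reactions$product %in% net$species$label))
  # every RC-consuming reaction produces exactly one OC
  rc_cons <- net$reactions[net$reactions$dRC < 0, ]
  expect_true(all(rc_cons$dRC == -1 & rc_cons$dOC == 1))
  expect_true(all(net$reactions$dOC[net$reactions$dRC == 0] == 0))
})

test_that("template application is order-independent", {
  sp <- pghs_species()
  shuffled <- sp[c(17, 3, 28, 1, 25, 9, 2, 14, 22, 5, 27, 11, 19, 7, 26, 4,
                   12, 20, 8, 15, 23, 6, 13, 21, 10, 16, 24, 18), ]
  a <- pghs_reactions(sp, pghs_parameters())
  b <- pghs_reactions(shuffled, pghs_parameters())
  expect_equal(a, b)
})

test_that("network diagnostics: absorbing FIE, reachability, severed routes", {
  net <- default_network()
  rep <- validate_pghs_network(net, quiet = TRUE)
  expect_equal(rep$fie_outdegree, 0)
  expect_length(rep$unreachable, 0)
  # a directed catalytic path exists from the resting state to the
  # POX_4/COX_2 hub state E12
  g <- rep$graph
  expect_true(is.finite(igraph::distances(g, "E1", "E12", mode = "out")[1, 1]))
  # removing the COX-death template severs the only route into COX-dead species
  net_nos3 <- net
  net_nos3$reactions <- net$reactions[net$reactions$template != "S3", ]
  rep2 <- validate_pghs_network(net_nos3, quiet = TRUE)
  expect_true(all(c("D1", "D2", "D3") %in% rep2$unreachable))
})

test_that("parameter set validates inputs and profiles", {
  p <- pghs_parameters()
  expect_equal(unname(p[names(table2_defaults)]), unname(table2_defaults))
  pa <- pghs_parameters("adrenaline_h2o2")
  expect_equal(unname(pa[c("k5", "k6", "k7", "k8")]),
               c(0.06, 0.001, 0.001, 0.001))
  expect_error(pghs_parameters(k2 = -1), "non-negative")
  expect_error(pghs_parameters(nosuch = 1), "unknown parameter")
  expect_error(pghs_reactions(pghs_species(), pghs_parameters(),
                              policy = "bogus"))
})
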