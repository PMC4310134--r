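test_that("scenario constructors encode the four transfer models", {
  none <- eet_scenario("none")
  expect_length(scenario_reactions(none), 0)
  cat1 <- eet_scenario("Cat1")
  expect_match(scenario_reactions(cat1), "2 e_ext \\+ nad -> nadh \\+ 2 hpp")
  cat2 <- eet_scenario("Cat2")
  expect_match(scenario_reactions(cat2), "2 e_ext \\+ nad -> nadh")
  expect_false(grepl("hpp", scenario_reactions(cat2)))
  an2 <- eet_scenario("An2")
  expect_match(scenario_reactions(an2), "nadh -> nad \\+ 2 e_ext")
  an1 <- eet_scenario("An1")
  expect_match(scenario_reactions(an1), "qh2 -> q \\+ 2 e_ext")
  expect_error(eet_scenario("Cat1", protons_per_atp = 0), "non-negative")
  expect_error(eet_scenario("An1", an1_pumping = -1), "non-negative")
})

test_that("Cat1 default coupling yields 2/3 ATP per NADH through the synthase", {
  # 2 protons per NADH, 3 protons per ATP: the periplasmic protons of one
  # Cat1 turnover drive exactly 2/3 ATP
  cat1 <- eet_scenario("Cat1")
  h <- rat_mul(2, 1, cat1$protons_per_electron$num, cat1$protons_per_electron$den)
  atp <- rat_div(h$num, h$den, cat1$protons_per_atp$num, cat1$protons_per_atp$den)
  expect_equal(c(atp$num, atp$den), c(2, 3))
})

test_that("Cat2 and An2 are mirror images through the electron exchange", {
  # identical stoichiometry with every coefficient negated
  stoich_of <- function(line) {
    net <- parse_network(line)
    st <- net$stoich[[1]]
    stats::setNames(st$num / st$den, st$ids)
  }
  c2 <- stoich_of(scenario_reactions("Cat2"))
  a2 <- stoich_of(scenario_reactions("An2"))
  expect_setequal(names(c2), names(a2))
  expect_equal(c2[names(a2)], -a2)
})

test_that("electrode electrons balance NAD(H) turnover two to one", {
  # toy: substrate oxidised to product only if NADH is drained by the anode
  net <- parse_network(c(
    "U: S_ext -> S | irrev | exchange",
    "R1: S + nad -> P + nadh | irrev | core",
    "XP: P -> P_ext | irrev | exchange",
    scenario_reactions("An2")))
  modes <- enumerate_efms(net)
  expect_equal(n_modes(modes), 1)
  v <- modes$fluxes[1, ]
  e_out <- 2 * v[["R_eet"]]           # 2 e- per EET turnover
  nadh_turn <- v[["R1"]]
  expect_equal(e_out, 2 * nadh_turn)
})

test_that("Cat2/An2 add no ATP-coupled reactions", {
  for (id in c("Cat2", "An2"))
    expect_false(any(grepl("atp|hpp", scenario_reactions(id))))
})

test_that("energetics calibration returns defaults for empty targets", {
  res <- calibrate_energetics(NULL, list())
  expect_true(res$within_tolerance)
  expect_equal(res$an1_pumping, 0)
})

test_that("energetics calibration selects the anchor-matching pumping ratio", {
  builder <- function(scenario, substrate, aerobic = FALSE,
                      aerobic_pumping = "5/2") {
    build_core_model(substrate, "none", scenario, aerobic = aerobic,
                     aerobic_pumping = aerobic_pumping)
  }
  anchor <- lp_max_yield(builder(eet_scenario("An1"), "glucose"),
                         "biomass_ext", "glc_ext")$yield_percent
  res <- calibrate_energetics(builder,
                              list(list(scenario = "An1",
                                        substrate = "glucose",
                                        yield = anchor)),
                              pump_grid = c(0, 1))
  expect_equal(res$an1_pumping, 0)
  expect_true(res$within_tolerance)
})
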