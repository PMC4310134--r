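test_that("build selects exactly one substrate uptake", {
  for (sub in c("glucose", "glycerol", "fumarate")) {
    net <- build_core_model(sub, "none", "none")
    ids <- net$rxns$id
    expect_equal("R2" %in% ids, sub == "glucose")     # PTS
    expect_equal("R64" %in% ids, sub == "glycerol")   # glycerol uptake
    expect_equal("R66" %in% ids, sub == "fumarate")   # fumarate uptake
    expect_equal(net$substrate_species,
                 c(glucose = "glc_ext", glycerol = "glyc_ext",
                   fumarate = "fum_ext")[[sub]])
  }
})

test_that("product pathways and EET reactions are appended on demand", {
  net <- build_core_model("glucose", "1,3-PDO", "Cat1")
  expect_true(all(c("P_pdo1", "P_pdo2", "R_eet") %in% net$rxns$id))
  expect_equal(net$product_species, "pdo_ext")
  expect_equal(net$scenario_id, "Cat1")
  # the appended pathways stay carbon balanced
  expect_true(validate_network(net)$ok)
  # native products append nothing
  net2 <- build_core_model("glucose", "ethanol", "none")
  expect_equal(net2$n_reactions, 73)  # 75 minus the two disabled uptakes
  expect_equal(net2$product_species, "etoh_ext")
})

test_that("unknown products and aerobic cathodes are rejected", {
  expect_error(build_core_model("glucose", "unobtainium", "none"),
               "unknown product")
  expect_error(build_core_model("glucose", "none", "Cat1", aerobic = TRUE),
               "cathodic")
  # aerobic anodic operation is allowed
  expect_silent(net <- build_core_model("glucose", "none", "An1",
                                        aerobic = TRUE))
  expect_true("R_cyo" %in% net$rxns$id)
})

test_that("all twenty products build and expose a carbon-bearing species", {
  expect_length(list_products(), 20)
  for (prod in list_products()) {
    net <- build_core_model("glucose", prod, "none")
    cc <- met_carbon(net, net$product_species)
    expect_gte(cc[["num"]] / cc[["den"]], 1)
  }
})

test_that("the glucose 1,3-PDO route consumes one ~P and two NADH per product", {
  # the condensed pathway must reproduce the lumped equation: half a glucose,
  # one energy-rich phosphate and two NADH per propanediol
  net <- build_core_model("glucose", "1,3-PDO", "none")
  res <- lp_max_yield(net, "pdo_ext", "glc_ext")
  v <- res$flux
  # in the optimal fermentation, PDO flux through the dehydratase equals the
  # NADH-consuming reductase flux
  expect_equal(v[["P_pdo2"]], sum(species_coeffs(net, "pdo_ext") * v),
               tolerance = 1e-9)
})

test_that("biomass ATP override changes the stoichiometry", {
  net <- build_core_model("glucose", "none", "none", biomass_atp = 70)
  st <- net$stoich[[match("R1", net$rxns$id)]]
  expect_equal(st$num[match("atp", st$ids)], -70)
  y70 <- lp_max_yield(net, "biomass_ext", "glc_ext")$yield_percent
  y <- lp_max_yield(build_core_model("glucose", "none", "none"),
                    "biomass_ext", "glc_ext")$yield_percent
  expect_lt(y70, y)
})
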