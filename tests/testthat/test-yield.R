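test_that("degree of reduction reproduces the reference species", {
  expect_equal(degree_of_reduction("C6H12O6"), 4)     # glucose
  expect_equal(degree_of_reduction("C2H6O"), 6)       # ethanol
  expect_equal(degree_of_reduction("C4H8O2"), 5)      # butyric acid
  expect_equal(degree_of_reduction("C4H10O2"), 5.5)   # 2,3-butanediol
  expect_equal(degree_of_reduction("CO2"), 0)
  expect_equal(degree_of_reduction("C3H8O3"), 14 / 3) # glycerol, exact
  expect_equal(degree_of_reduction(c(C = 1, H = 4)), 8)  # methane
  expect_error(degree_of_reduction("H2O"), "carbon-free")
})

test_that("carbon yield follows the flux-weighted carbon balance", {
  net <- toy_ferment_network()
  modes <- enumerate_efms(net)
  expect_equal(n_modes(modes), 1)
  # S (6 C) -> 2 P (2 C each) + 2 CO2-like C1: product yield 4/6
  y <- carbon_yield(modes, net, "P_ext", "S_ext")
  expect_equal(y, 100 * 4 / 6, tolerance = 1e-12)
  yc <- carbon_yield(modes, net, "C_ext", "S_ext")
  expect_equal(yc, 100 * 2 / 6, tolerance = 1e-12)
})

test_that("modes not consuming the substrate yield NA", {
  net <- parse_network(c("U: A_ext -> A | irrev | exchange",
                         "X: A -> B_ext | irrev | exchange",
                         "U2: C_ext -> C2 | irrev | exchange",
                         "X2: C2 -> D_ext | irrev | exchange"))
  net <- set_compositions(net, data.frame(
    id = c("A_ext", "A", "B_ext", "C_ext", "C2", "D_ext"),
    C = 1, H = 0, O = 0, N = 0, S = 0, P = 0))
  modes <- enumerate_efms(net)
  y <- carbon_yield(modes, net, "B_ext", "A_ext")
  expect_true(any(is.na(y)))   # the C-consuming mode does not touch A
  expect_true(any(!is.na(y)))
})

test_that("by-product spectrum closes the carbon balance at 100%", {
  net <- toy_ferment_network()
  modes <- enumerate_efms(net)
  spec <- by_product_spectrum(modes$fluxes[1, , drop = FALSE], net, "S_ext")
  expect_equal(sum(spec), 100, tolerance = 1e-9)
  expect_equal(sort(names(spec)), c("C_ext", "P_ext"))
})

test_that("max_yield picks the top mode and matches the LP", {
  net <- set_compositions(diamond_network(), diamond_compositions())
  modes <- enumerate_efms(net)
  res <- max_yield(modes, net, "D_ext", "E_ext")
  expect_equal(res$yield_percent, 100, tolerance = 1e-12)
  expect_false(is.null(res$mode_ref))
  expect_equal(res$yield_percent,
               lp_max_yield(net, "D_ext", "E_ext")$yield_percent,
               tolerance = 1e-9)
  # singleton set returns that mode's yield
  solo <- max_yield(modes$fluxes[1, , drop = FALSE], net, "D_ext", "E_ext")
  expect_equal(solo$yield_percent, 100, tolerance = 1e-12)
})

test_that("growth-coupled restriction reports 'none' without growth modes", {
  net <- toy_ferment_network()
  modes <- enumerate_efms(net)
  res <- growth_coupled_max_yield(modes, net, "P_ext", "S_ext")
  expect_equal(res$status, "none")
})

test_that("mode census counts secreting modes and handles empty sets", {
  net <- set_compositions(diamond_network(), diamond_compositions())
  modes <- enumerate_efms(net)
  cen <- mode_census(modes, net, "D_ext")
  expect_equal(cen$count, 2)
  expect_equal(cen$fraction, 1)
  cen2 <- mode_census(modes, net, function(v, n) v[["R1"]] > 0)
  expect_equal(cen2$count, 1)
  expect_equal(cen2$fraction, 0.5)
  empty <- modes$fluxes[0, , drop = FALSE]
  expect_true(is.na(mode_census(empty, net, "D_ext")$fraction))
})

test_that("mode normalization scales substrate uptake to one", {
  net <- toy_ferment_network()
  modes <- enumerate_efms(net)
  nm <- normalize_modes(modes, net, "S_ext")
  expect_equal(nm$normalized_by, rep("substrate", n_modes(modes)))
  for (i in seq_len(n_modes(modes))) {
    v <- nm$num[i, ] * nm$scale_den[i] / nm$scale_num[i]
    uptake <- -sum(species_coeffs(net, "S_ext") * v)
    expect_equal(uptake, 1, tolerance = 1e-12)
  }
  # without a substrate the smallest positive flux becomes one
  nm2 <- normalize_modes(modes, net)
  expect_equal(nm2$normalized_by, rep("min-flux", n_modes(modes)))
  v2 <- nm2$num[1, ] * nm2$scale_den[1] / nm2$scale_num[1]
  expect_equal(min(abs(v2[v2 != 0])), 1)
})

test_that("scatter table has one row per mode and an empty case", {
  net <- toy_ferment_network()
  modes <- enumerate_efms(net)
  st <- scatter_table(modes, net, "P_ext", "S_ext")
  expect_equal(nrow(st), n_modes(modes))
  expect_named(st, c("mode", "biomass_yield", "product_yield"))
  st0 <- scatter_table(modes$fluxes[0, , drop = FALSE], net, "P_ext", "S_ext")
  expect_equal(nrow(st0), 0)
})
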