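test_that("single linear path gives exactly one mode", {
  e <- enumerate_efms(chain_network())
  expect_equal(n_modes(e), 1)
  expect_equal(unname(e$fluxes[1, ]), c(1, 1, 1))
})

test_that("diamond network has exactly its two route modes", {
  e <- enumerate_efms(diamond_network())
  expect_equal(n_modes(e), 2)
  # frozen from exhaustive support enumeration (each route: U,Ri,Rj,X at 1)
  expect_same_modes(e, brute_force_efms(diamond_network()))
})

test_that("splitting reversible reactions and folding round-trips", {
  net <- load_core_network()
  sp <- split_reversible(net)
  expect_equal(sp$network$n_reactions, 99)  # 75 + 24 backward columns
  expect_true(all(!sp$network$rxns$reversible))
  v <- matrix(rnorm(99), nrow = 1)
  v_orig <- fold_modes(v, sp$mapping, 75)
  # a vector living only on forward columns folds to itself
  w <- matrix(0, 1, 99); w[1, 3] <- 2
  expect_equal(fold_modes(w, sp$mapping, 75)[1, 3], 2)
  expect_equal(ncol(v_orig), 75)
})

test_that("reversible reactions yield sign-canonical modes, no two-cycles", {
  net <- parse_network(c("U: E_ext -> A | irrev | exchange",
                         "R1: A -> B | rev | core",
                         "X: B -> B_ext | irrev | exchange",
                         "Y: A -> A2_ext | irrev | exchange"))
  e <- enumerate_efms(net)
  expect_equal(n_modes(e), 2)
  # no mode is the futile forward/backward cycle of R1
  expect_true(all(rowSums(e$fluxes != 0) >= 2))
  expect_same_modes(e, brute_force_efms(net))
})

test_that("enumeration is invariant under reaction and metabolite order", {
  lines <- c("U: E_ext -> A | irrev | exchange",
             "R1: A -> B | irrev | core",
             "R2: A -> C | irrev | core",
             "R3: B -> D | irrev | core",
             "R4: C -> D | irrev | core",
             "X: D -> D_ext | irrev | exchange")
  a <- enumerate_efms(parse_network(lines))
  b <- enumerate_efms(parse_network(rev(lines)))
  # compare as sets of named flux patterns
  key <- function(e) {
    apply(e$fluxes, 1, function(v)
      paste(sort(paste0(e$reaction_ids[v != 0], "=", v[v != 0])),
            collapse = ","))
  }
  expect_setequal(key(a), key(b))
})

test_that("adding a strictly redundant duplicate preserves original modes", {
  base <- diamond_network()
  dup <- parse_network(c("U: E_ext -> A | irrev | exchange",
                         "R1: A -> B | irrev | core",
                         "R2: A -> C | irrev | core",
                         "R3: B -> D | irrev | core",
                         "R4: C -> D | irrev | core",
                         "R1b: A -> B | irrev | core",
                         "X: D -> D_ext | irrev | exchange"))
  e0 <- enumerate_efms(base)
  e1 <- enumerate_efms(dup)
  patt <- function(e, drop) {
    keep <- setdiff(e$reaction_ids, drop)
    unique(apply(e$fluxes[, keep, drop = FALSE], 1, paste, collapse = ","))
  }
  # modes of the duplicate network that avoid R1b are exactly the originals
  no_dup <- e1$fluxes[e1$fluxes[, "R1b"] == 0, colnames(e0$fluxes)]
  expect_setequal(apply(no_dup, 1, paste, collapse = ","),
                  apply(e0$fluxes, 1, paste, collapse = ","))
  # every extra mode uses the duplicate
  expect_true(all(e1$fluxes[!(apply(e1$fluxes[, colnames(e0$fluxes)], 1,
                                    paste, collapse = ",") %in%
                                apply(e0$fluxes, 1, paste, collapse = ",")),
                            "R1b"] != 0))
})

test_that("is_elementary accepts modes and rejects composites", {
  chain <- chain_network()
  expect_true(is_elementary(chain, c(U = 1, C1 = 1, X = 1)))
  d <- diamond_network()
  e <- enumerate_efms(d)
  for (i in seq_len(n_modes(e)))
    expect_true(is_elementary(d, e$fluxes[i, ]))
  combo <- e$fluxes[1, ] + e$fluxes[2, ]
  expect_false(is_elementary(d, combo))
  # steady-state violation is an error, not FALSE
  expect_error(is_elementary(d, c(U = 1, R1 = 0, R2 = 0, R3 = 0, R4 = 0,
                                  X = 0)),
               "steady state")
  expect_error(is_elementary(d, -e$fluxes[1, ]), "irreversibility")
})

test_that("resource guard trips on an absurd ray ceiling", {
  net <- build_core_model("glucose", "none", "none")
  expect_error(enumerate_efms(net, max_rays = 10), "ray ceiling")
})
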