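test_that("a small LP screen covers every requested cell", {
  rep <- screen_all("glucose", c("1,3-PDO", "2,3-BDO"),
                    c("none", "Cat1", "An2"), method = "lp")
  expect_s3_class(rep, "ScreenReport")
  expect_equal(nrow(rep$cells), 6)
  expect_true(all(rep$cells$status == "ok"))
  expect_equal(nrow(rep$benefit), 2)
})

test_that("butanediol isomers are assigned opposite electrodes", {
  rep <- screen_all("glucose", c("1,4-BDO", "2,3-BDO"),
                    c("none", "Cat1", "Cat2", "An1", "An2"), method = "lp")
  b <- rep$benefit
  expect_equal(b$benefit[b$product == "1,4-BDO"], "cathode")
  expect_equal(b$benefit[b$product == "2,3-BDO"], "anode")
})

test_that("redox-balanced native products show no electrode benefit", {
  rep <- screen_all("glucose", "ethanol",
                    c("none", "Cat1", "Cat2", "An1", "An2"), method = "lp")
  expect_equal(rep$benefit$benefit, "none")
})

test_that("empty request lists are rejected before compute", {
  expect_error(screen_all("glucose", character(0), "none"), "non-empty")
  expect_error(screen_all(character(0), "ethanol", "none"), "non-empty")
})

test_that("screen reports serialize to TSV and JSON", {
  rep <- screen_all("glucose", "succinate", c("none", "An1"), method = "lp")
  tsv <- tempfile(fileext = ".tsv")
  js <- tempfile(fileext = ".json")
  write_screen(rep, tsv, "tsv")
  write_screen(rep, js, "json")
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), 2)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(parsed$cells), 2)
  unlink(c(tsv, js))
})

test_that("mode sets serialize with supports intact", {
  net <- toy_ferment_network()
  modes <- enumerate_efms(net)
  tsv <- tempfile(fileext = ".tsv")
  write_modes(modes, tsv, "tsv")
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), n_modes(modes))
  js <- tempfile(fileext = ".json")
  write_modes(modes, js, "json")
  parsed <- jsonlite::read_json(js)
  expect_length(parsed, n_modes(modes))
  unlink(c(tsv, js))
})

test_that("run configs validate and a configured run is deterministic", {
  cfg_file <- tempfile(fileext = ".yaml")
  out1 <- file.path(tempdir(), "run1"); out2 <- file.path(tempdir(), "run2")
  writeLines(c("substrates: [glucose]",
               "products: ['succinate']",
               "scenarios: [none, An1]",
               "method: lp",
               sprintf("out_dir: %s", out1)), cfg_file)
  cfg <- read_run_config(cfg_file)
  expect_equal(cfg$method, "lp")
  run_screen(cfg)
  cfg$out_dir <- out2
  run_screen(cfg)
  expect_identical(readLines(file.path(out1, "screen.tsv")),
                   readLines(file.path(out2, "screen.tsv")))
  expect_true(file.exists(file.path(out1, "run_log.txt")))
  # invalid configs fail before compute
  writeLines(c("products: ['unobtainium']"), cfg_file)
  expect_error(read_run_config(cfg_file), "unknown product")
  writeLines(c("products: []"), cfg_file)
  expect_error(read_run_config(cfg_file))
  unlink(c(cfg_file, out1, out2), recursive = TRUE)
})
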