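# The substrate x product x scenario screen and its reporting surface.

.SCENARIOS_DEFAULT <- c("none", "Cat1", "Cat2", "An1", "An2")

# yield comparison tolerance in percentage points (absorbs one-decimal
# rounding of reported values)
.YIELD_TOL <- 0.5

#' Screen products across substrates and EET scenarios
#'
#' For every (substrate, product, scenario) cell the maximum carbon yield
#' and the growth-coupled maximum are computed, either from the LP ceiling
#' (\code{method = "lp"}, fast) or from full elementary mode enumeration
#' (\code{method = "efm"}, also reports mode counts and the top mode's
#' by-product spectrum).  Each (substrate, product) pair is flagged with its
#' most beneficial electrode option: cathodic, anodic, or no benefit.
#'
#' @param substrates character vector from
#'   \code{c("glucose", "glycerol", "fumarate")}.
#' @param products character vector from \code{\link{list_products}()}.
#' @param scenarios character vector of scenario ids.
#' @param method \code{"lp"} or \code{"efm"}.
#' @param max_rays enumeration resource ceiling (\code{method = "efm"}).
#' @param min_biomass biomass threshold defining growth coupling for the LP
#'   route.
#' @param scenario_args list of arguments passed to
#'   \code{\link{eet_scenario}} (coupling overrides).
#' @return a \code{ScreenReport}: data frame of cells plus a benefit table.
#' @export
screen_all <- function(substrates = c("glucose", "glycerol"),
                       products = list_products(),
                       scenarios = .SCENARIOS_DEFAULT,
                       method = c("lp", "efm"), max_rays = 5e5,
                       min_biomass = 1e-4, scenario_args = list()) {
  method <- match.arg(method)
  if (!length(substrates) || !length(products) || !length(scenarios))
    stop("substrates, products and scenarios must be non-empty", call. = FALSE)
  rows <- list()
  for (sub in substrates) for (prod in products) for (scen in scenarios) {
    cell <- list(substrate = sub, product = prod, scenario = scen,
                 max_yield = NA_real_, growth_coupled_yield = NA_real_,
                 n_modes = NA_integer_, by_products = NA_character_,
                 status = "ok")
    res <- try({
      scn <- do.call(eet_scenario, c(list(id = scen), scenario_args))
      net <- build_core_model(sub, prod, scn)
      psp <- net$product_species
      ssp <- net$substrate_species
      if (method == "lp") {
        cell$max_yield <- lp_max_yield(net, psp, ssp)$yield_percent
        gc <- lp_max_yield(net, psp, ssp, require_biomass = min_biomass)
        cell$growth_coupled_yield <- gc$yield_percent
      } else {
        modes <- enumerate_efms(net, max_rays = max_rays)
        cell$n_modes <- n_modes(modes)
        my <- max_yield(modes, net, psp, ssp)
        cell$max_yield <- my$yield_percent
        gc <- growth_coupled_max_yield(modes, net, psp, ssp)
        cell$growth_coupled_yield <- gc$yield_percent
        if (!is.null(my$mode_ref)) {
          spec <- by_product_spectrum(my$mode_ref, net, ssp)
          spec <- spec[setdiff(names(spec), psp)]
          cell$by_products <- paste(sprintf("%s=%.1f", names(spec), spec),
                                    collapse = ";")
        }
      }
      NULL
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      cell$status <- conditionMessage(attr(res, "condition"))
    rows[[length(rows) + 1L]] <- cell
  }
  cells <- do.call(rbind, lapply(rows, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  structure(list(cells = cells, benefit = .benefit_table(cells),
                 method = method),
            class = "ScreenReport")
}

# classify each substrate/product pair by its best electrode side
.benefit_table <- function(cells) {
  pairs <- unique(cells[, c("substrate", "product")])
  out <- NULL
  for (r in seq_len(nrow(pairs))) {
    sel <- cells$substrate == pairs$substrate[r] &
      cells$product == pairs$product[r] & cells$status == "ok"
    cc <- cells[sel, ]
    base <- cc$max_yield[cc$scenario == "none"]
    if (!length(base) || is.na(base)) base <- -Inf
    cat_max <- suppressWarnings(max(cc$max_yield[cc$scenario %in%
                                                   c("Cat1", "Cat2")], na.rm = TRUE))
    an_max <- suppressWarnings(max(cc$max_yield[cc$scenario %in%
                                                  c("An1", "An2")], na.rm = TRUE))
    best <- if (is.finite(cat_max) && cat_max > base + .YIELD_TOL &&
                cat_max >= an_max) "cathode"
            else if (is.finite(an_max) && an_max > base + .YIELD_TOL) "anode"
            else "none"
    out <- rbind(out, data.frame(substrate = pairs$substrate[r],
                                 product = pairs$product[r],
                                 no_eet = if (is.finite(base)) base else NA_real_,
                                 cathode_max = if (is.finite(cat_max)) cat_max else NA_real_,
                                 anode_max = if (is.finite(an_max)) an_max else NA_real_,
                                 benefit = best, stringsAsFactors = FALSE))
  }
  out
}

#' @export
print.ScreenReport <- function(x, ...) {
  cat(sprintf("ScreenReport (%s): %d cells, %d substrate/product pairs\n",
              x$method, nrow(x$cells), nrow(x$benefit)))
  tab <- table(x$benefit$benefit)
  cat("  benefit:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Write a screen report to TSV and/or JSON
#'
#' @param report a \code{ScreenReport}.
#' @param path output file path (extension chooses nothing; see
#'   \code{format}).
#' @param format \code{"tsv"} or \code{"json"}.
#' @export
write_screen <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(report$cells, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    jsonlite::write_json(list(cells = report$cells, benefit = report$benefit),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Write a mode set as TSV (one row per mode) or compact JSON
#'
#' Fluxes are written as primitive integers by default; with a network (and
#' optionally a substrate) they are normalized per
#' \code{\link{normalize_modes}} and rendered either as decimals or as exact
#' \code{p/q} strings.
#'
#' @param modes an \code{efm_set}.
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @param network optional owning network, enables normalization.
#' @param substrate substrate species id for substrate normalization.
#' @param rational render normalized fluxes as exact \code{p/q} strings
#'   instead of decimals (TSV only).
#' @export
write_modes <- function(modes, path, format = c("tsv", "json"),
                        network = NULL, substrate = NULL, rational = FALSE) {
  format <- match.arg(format)
  V <- modes$fluxes
  sn <- rep(1, nrow(V)); sd <- rep(1, nrow(V))
  if (!is.null(network)) {
    nm <- normalize_modes(modes, network, substrate)
    sn <- nm$scale_num; sd <- nm$scale_den
  }
  if (format == "tsv") {
    df <- if (rational) {
      as.data.frame(lapply(seq_len(ncol(V)), function(j) {
        r <- rat_reduce(V[, j] * sd, sn)
        rat_format(r$num, r$den)
      }), col.names = colnames(V), optional = TRUE)
    } else as.data.frame(V * sd / sn)
    utils::write.table(cbind(mode = seq_len(nrow(V)), df), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    out <- lapply(seq_len(nrow(V)), function(i) {
      nz <- which(V[i, ] != 0)
      list(support = colnames(V)[nz],
           flux = unname(V[i, nz] * sd[i] / sn[i]))
    })
    jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

# stable content hash (polynomial rolling hash over the serialized table,
# exact in double arithmetic)
.network_hash <- function(network) {
  bytes <- utf8ToInt(paste(format_network(network), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 67108859
  sprintf("%08x", h)
}

#' Read and validate a run configuration file
#'
#' YAML key-value file with keys \code{substrates}, \code{products},
#' \code{scenarios}, \code{method}, \code{max_rays}, \code{out_dir},
#' \code{formats} and an optional \code{eet} block
#' (\code{protons_per_electron}, \code{protons_per_atp},
#' \code{an1_pumping}).  Missing keys take the screen defaults.
#'
#' @param path path to the YAML config.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(substrates = c("glucose", "glycerol"),
                   products = list_products(),
                   scenarios = .SCENARIOS_DEFAULT,
                   method = "lp", max_rays = 5e5, out_dir = ".",
                   formats = "tsv", eet = list())
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  stopifnot(length(cfg$products) >= 1, length(cfg$substrates) >= 1,
            cfg$method %in% c("lp", "efm"),
            all(cfg$scenarios %in% .SCENARIOS_DEFAULT),
            all(cfg$formats %in% c("tsv", "json")))
  unknown <- setdiff(cfg$products, list_products())
  if (length(unknown))
    stop(sprintf("unknown product(s) in config: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  cfg
}

#' Run a configured screen and write its report files
#'
#' Deterministic: identical configuration yields byte-identical reports.
#' Writes \code{screen.tsv}/\code{screen.json} plus \code{run_log.txt}
#' recording the network hash, scenario parameters and per-cell status.
#'
#' @param config a config list from \code{\link{read_run_config}}, or a path
#'   to a YAML config file.
#' @return the \code{ScreenReport}, invisibly.
#' @export
run_screen <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  eet_args <- config$eet[intersect(names(config$eet),
                                   c("protons_per_electron", "protons_per_atp",
                                     "an1_pumping"))]
  report <- screen_all(config$substrates, config$products, config$scenarios,
                       method = config$method, max_rays = config$max_rays,
                       scenario_args = eet_args)
  for (fmt in config$formats)
    write_screen(report, file.path(config$out_dir, paste0("screen.", fmt)),
                 format = fmt)
  log <- c(sprintf("network_hash: %s", .network_hash(load_core_network())),
           sprintf("method: %s", config$method),
           sprintf("eet_overrides: %s",
                   if (length(eet_args)) paste(names(eet_args), unlist(eet_args),
                                               sep = "=", collapse = " ")
                   else "(defaults)"),
           sprintf("cells: %d  failed: %d", nrow(report$cells),
                   sum(report$cells$status != "ok")))
  writeLines(log, file.path(config$out_dir, "run_log.txt"))
  invisible(report)
}
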