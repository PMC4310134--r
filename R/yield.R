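# Yield analytics: degree of reduction, carbon yields of elementary modes,
# maximum and growth-coupled maxima, by-product spectra and mode census
# statistics.
#
# Mode fluxes are primitive integer vectors, so every net exchange rate is an
# exact rational; yields are evaluated rationally and only converted to
# doubles on return.

#' Degree of reduction of a compound
#'
#' Available electrons per carbon atom,
#' \eqn{DoR = (4a + b - 2c - 3d + 6e + 5f)/a} for a compound
#' \eqn{C_a H_b O_c N_d S_e P_f}: C contributes +4, H +1, O -2, N -3, S +6
#' and P +5.  Glucose scores 4, ethanol 6, butyric acid 5, carbon dioxide 0.
#'
#' @param comp an elemental formula string (e.g. \code{"C4H10O2"}) or a named
#'   numeric vector with elements \code{C}, \code{H}, \code{O}, \code{N},
#'   \code{S}, \code{P}.
#' @return the degree of reduction (electrons per carbon).
#' @examples
#' degree_of_reduction("C6H12O6")  # glucose: 4
#' degree_of_reduction("C4H10O2")  # 2,3-butanediol: 5.5
#' @export
degree_of_reduction <- function(comp) {
  if (is.character(comp)) comp <- parse_formula(comp)
  need <- c("C", "H", "O", "N", "S", "P")
  missing <- setdiff(need, names(comp))
  full <- c(comp, stats::setNames(rep(0, length(missing)), missing))
  if (anyNA(full[need]))
    stop("composition has unknown element counts", call. = FALSE)
  if (full[["C"]] < 1)
    stop("degree of reduction undefined for carbon-free species", call. = FALSE)
  (4 * full[["C"]] + full[["H"]] - 2 * full[["O"]] - 3 * full[["N"]] +
     6 * full[["S"]] + 5 * full[["P"]]) / full[["C"]]
}

# rational exchange coefficients of one species across reactions
.species_coeff_rat <- function(network, species) {
  num <- numeric(network$n_reactions)
  den <- rep(1, network$n_reactions)
  for (j in seq_len(network$n_reactions)) {
    st <- network$stoich[[j]]
    k <- match(species, st$ids)
    if (!is.na(k)) { num[j] <- st$num[k]; den[j] <- st$den[k] }
  }
  list(num = num, den = den)
}

# exact net production rates of a species for integer mode matrix V
# returns list(num = integer vector, den = scalar)
.production_rat <- function(network, V, species) {
  cf <- .species_coeff_rat(network, species)
  L <- 1
  for (d in unique(cf$den)) {
    .rat_guard(L, d)
    L <- L / gcd_int(L, d) * d
  }
  cint <- cf$num * (L / cf$den)
  if (length(V))
    .rat_guard(max(abs(V), 0) * max(abs(cint), 1) * ncol(V))
  list(num = drop(V %*% cint), den = L)
}

.as_flux_matrix <- function(modes) {
  if (inherits(modes, "efm_set")) return(modes$fluxes)
  if (is.matrix(modes)) return(modes)
  matrix(modes, nrow = 1, dimnames = list(NULL, names(modes)))
}

#' Carbon yield of elementary modes
#'
#' \eqn{Yield = 100 \cdot flux_p C_p / (flux_s C_s)} where \eqn{flux_p} is
#' the net production rate of the product species, \eqn{flux_s} the net
#' consumption rate of the substrate and \eqn{C} carbon atom counts (biomass
#' carbon is the C-mol content of the biomass equation).  Modes that do not
#' consume the substrate get \code{NA}.
#'
#' @param modes an \code{efm_set}, a mode matrix or a single flux vector.
#' @param network the \code{MetabolicNetwork} the modes belong to.
#' @param product product species id (e.g. \code{"pdo_ext"},
#'   \code{"biomass_ext"}).
#' @param substrate substrate species id (e.g. \code{"glc_ext"}).
#' @return numeric vector of carbon yields in percent, one per mode.
#' @export
carbon_yield <- function(modes, network, product, substrate) {
  V <- .as_flux_matrix(modes)
  prod <- .production_rat(network, V, product)
  cons <- .production_rat(network, V, substrate)
  cp <- met_carbon(network, product)
  cs <- met_carbon(network, substrate)
  if (is.na(cp[["num"]]) || is.na(cs[["num"]]))
    stop("product or substrate has unknown carbon content", call. = FALSE)
  uptake <- -cons$num / cons$den
  y <- 100 * (prod$num / prod$den) * (cp[["num"]] / cp[["den"]]) /
    (uptake * (cs[["num"]] / cs[["den"]]))
  y[uptake <= 0] <- NA_real_
  y
}

# number of distinct secreted carbon species other than the product
.n_byproducts <- function(network, v, product) {
  ext <- network$mets$id[network$mets$external]
  cnt <- 0L
  for (sp in setdiff(ext, product)) {
    cc <- met_carbon(network, sp)
    if (is.na(cc[["num"]]) || cc[["num"]] == 0) next
    pr <- .production_rat(network, matrix(v, nrow = 1), sp)
    if (pr$num > 0) cnt <- cnt + 1L
  }
  cnt
}

.pick_top_mode <- function(V, yields, network, product) {
  best <- max(yields, na.rm = TRUE)
  cand <- which(!is.na(yields) & yields >= best - 1e-12)
  if (length(cand) > 1L) {
    nb <- vapply(cand, function(i) .n_byproducts(network, V[i, ], product), 0L)
    cand <- cand[nb == min(nb)]
  }
  cand[1L]  # rows are already in canonical support order
}

#' Maximum carbon yield over a set of elementary modes
#'
#' Ties are broken toward modes with fewer by-product species, then by the
#' canonical mode order; the achieving mode is reported as the top mode.
#'
#' @inheritParams carbon_yield
#' @return a \code{YieldResult} with \code{yield_percent}, the top mode flux
#'   vector (\code{mode_ref}) and its index in the mode set.
#' @export
max_yield <- function(modes, network, product, substrate) {
  V <- .as_flux_matrix(modes)
  y <- if (nrow(V)) carbon_yield(V, network, product, substrate) else numeric(0)
  if (!length(y) || all(is.na(y)))
    return(structure(list(product = product, substrate = substrate,
                          yield_percent = NA_real_, mode_ref = NULL,
                          status = "no substrate-consuming mode"),
                     class = "YieldResult"))
  top <- .pick_top_mode(V, y, network, product)
  structure(list(product = product, substrate = substrate,
                 yield_percent = y[top],
                 mode_ref = stats::setNames(V[top, ], colnames(V)),
                 mode_index = top, status = "optimal"),
            class = "YieldResult")
}

#' Growth-coupled maximum yield
#'
#' Maximum carbon yield restricted to modes with strictly positive biomass
#' formation.
#'
#' @inheritParams carbon_yield
#' @return a \code{YieldResult}; status \code{"none"} when no mode grows.
#' @export
growth_coupled_max_yield <- function(modes, network, product, substrate) {
  V <- .as_flux_matrix(modes)
  if (nrow(V)) {
    bm <- .production_rat(network, V, "biomass_ext")
    keep <- bm$num > 0
    V <- V[keep, , drop = FALSE]
  }
  res <- max_yield(V, network, product, substrate)
  if (is.na(res$yield_percent)) res$status <- "none"
  res$growth_coupled <- TRUE
  res
}

#' By-product spectrum of one mode
#'
#' Carbon fractions of every secreted external species (biomass included),
#' in percent of the substrate carbon consumed.  For a carbon-conserving
#' network the fractions sum to 100.
#'
#' @param mode a single flux vector (or one-row matrix / efm_set).
#' @inheritParams carbon_yield
#' @return named numeric vector of carbon percentages.
#' @export
by_product_spectrum <- function(mode, network, substrate) {
  V <- .as_flux_matrix(mode)
  stopifnot(nrow(V) == 1L)
  ext <- network$mets$id[network$mets$external]
  out <- numeric(0)
  for (sp in setdiff(ext, substrate)) {
    cc <- met_carbon(network, sp)
    if (is.na(cc[["num"]]) || cc[["num"]] == 0) next
    y <- carbon_yield(V, network, sp, substrate)
    if (!is.na(y) && y > 0) out[sp] <- y
  }
  sort(out, decreasing = TRUE)
}

#' Normalize elementary modes for reporting
#'
#' Scales each mode so that substrate uptake equals one when the mode
#' consumes the substrate, and so that the smallest positive flux equals one
#' otherwise.  Fluxes stay exact: the integer mode vector is returned
#' together with a per-mode rational scale.
#'
#' @param modes an \code{efm_set} or mode matrix.
#' @param network the owning network.
#' @param substrate substrate species id, or \code{NULL} to normalize every
#'   mode by its smallest positive flux.
#' @return list with \code{num} (integer mode matrix), the exact rational
#'   per-mode scale (\code{scale_num}, \code{scale_den}; normalized flux =
#'   flux * scale_den / scale_num) and \code{normalized_by}
#'   (\code{"substrate"} or \code{"min-flux"} per mode).
#' @export
normalize_modes <- function(modes, network, substrate = NULL) {
  V <- .as_flux_matrix(modes)
  sn <- rep(1, nrow(V)); sd <- rep(1, nrow(V))
  by <- rep("min-flux", nrow(V))
  if (!is.null(substrate)) {
    pr <- .production_rat(network, V, substrate)
    up_num <- -pr$num
    for (i in seq_len(nrow(V))) {
      if (up_num[i] > 0) {
        r <- rat_reduce(up_num[i], pr$den)
        sn[i] <- r$num; sd[i] <- r$den
        by[i] <- "substrate"
      }
    }
  }
  for (i in which(by == "min-flux")) {
    pos <- abs(V[i, V[i, ] != 0])
    if (length(pos)) sn[i] <- min(pos)
  }
  list(num = V, scale_num = sn, scale_den = sd, normalized_by = by)
}

#' Census of modes satisfying a predicate
#'
#' @param modes an \code{efm_set} or mode matrix.
#' @param network the owning network.
#' @param predicate either a function \code{(flux, network) -> logical} or a
#'   species id, shorthand for "secretes that species".
#' @return list with \code{count} and \code{fraction} (NA for an empty set).
#' @export
mode_census <- function(modes, network, predicate) {
  V <- .as_flux_matrix(modes)
  if (!nrow(V)) return(list(count = 0L, fraction = NA_real_))
  hit <- if (is.character(predicate)) {
    pr <- .production_rat(network, V, predicate)
    pr$num > 0
  } else {
    vapply(seq_len(nrow(V)), function(i)
      isTRUE(predicate(stats::setNames(V[i, ], colnames(V)), network)), TRUE)
  }
  list(count = sum(hit), fraction = sum(hit) / nrow(V))
}

#' Biomass/product yield table of a mode set
#'
#' One row per mode: biomass yield and product yield, ready for plotting the
#' classic biomass-against-product scatter of a mode set.
#'
#' @inheritParams carbon_yield
#' @return data frame with columns \code{mode}, \code{biomass_yield} and
#'   \code{product_yield} (percent).
#' @export
scatter_table <- function(modes, network, product, substrate) {
  V <- .as_flux_matrix(modes)
  if (!nrow(V))
    return(data.frame(mode = integer(0), biomass_yield = numeric(0),
                      product_yield = numeric(0)))
  bm <- if ("biomass_ext" %in% network$mets$id)
    carbon_yield(V, network, "biomass_ext", substrate) else rep(0, nrow(V))
  data.frame(mode = seq_len(nrow(V)),
             biomass_yield = bm,
             product_yield = carbon_yield(V, network, product, substrate))
}
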