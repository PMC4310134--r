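# Linear-programming oracle for maximum carbon yields.
#
# Over the steady-state flux cone with substrate uptake fixed to 1, the
# maximum carbon yield of a product is a linear programme; by cone theory its
# optimum equals the maximum yield over the elementary modes, which makes the
# LP an independent cross-check of the enumeration engine (and a fast
# stand-in where a network is too large to enumerate comfortably).
#
# The solver is a dense two-phase primal simplex with Bland's anti-cycling
# rule, written for equality-constrained problems in nonnegative variables.
# Stoichiometric LPs are small (tens of rows, ~100 columns) but degenerate;
# Bland's rule makes termination certain and the solution deterministic.
# Optima are verified against the steady-state residual tolerance, and every
# screened maximum is cross-checked against enumerated modes in the tests.

# minimize c'x subject to A x = b, x >= 0
# returns list(status = "optimal"|"infeasible"|"unbounded", x, value)
.simplex_two_phase <- function(A, b, cvec, eps = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  N <- n + m                        # real + artificial columns
  Tab <- cbind(A, diag(m), b, deparse.level = 0)
  basis <- n + seq_len(m)
  live_rows <- rep(TRUE, m)

  pivot <- function(Tab, r, j) {
    Tab[r, ] <- Tab[r, ] / Tab[r, j]
    for (i in seq_len(nrow(Tab))) {
      if (i != r && abs(Tab[i, j]) > 0) Tab[i, ] <- Tab[i, ] - Tab[i, j] * Tab[r, ]
    }
    Tab
  }

  run_phase <- function(Tab, basis, cost, allowed) {
    repeat {
      rows <- seq_along(basis)
      red <- cost - drop(crossprod(cost[basis], Tab[rows, seq_len(N), drop = FALSE]))
      enter <- which(allowed & red < -eps)
      if (!length(enter)) return(list(Tab = Tab, basis = basis, status = "optimal"))
      j <- min(enter)               # Bland
      col <- Tab[rows, j]
      cand <- which(col > eps)
      if (!length(cand)) return(list(Tab = Tab, basis = basis, status = "unbounded"))
      ratio <- Tab[cand, N + 1] / col[cand]
      best <- cand[ratio <= min(ratio) + eps]
      r <- best[which.min(basis[best])]  # Bland tie-break
      Tab <- pivot(Tab, r, j)
      basis[r] <- j
    }
  }

  # phase 1: drive artificials to zero
  cost1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(Tab, basis, cost1, allowed = rep(TRUE, N))
  Tab <- ph1$Tab; basis <- ph1$basis
  ph1_val <- sum(Tab[basis > n, N + 1])
  if (ph1_val > 1e-7) return(list(status = "infeasible", x = NULL, value = NA_real_))
  # pivot remaining artificials out of the basis (or drop redundant rows)
  drop_rows <- integer(0)
  for (r in seq_along(basis)) {
    if (basis[r] <= n) next
    j <- which(abs(Tab[r, seq_len(n)]) > eps)
    if (length(j)) {
      Tab <- pivot(Tab, r, j[1])
      basis[r] <- j[1]
    } else drop_rows <- c(drop_rows, r)
  }
  if (length(drop_rows)) {
    Tab <- Tab[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }

  cost2 <- c(cvec, rep(0, m))
  allowed <- c(rep(TRUE, n), rep(FALSE, m))
  ph2 <- run_phase(Tab, basis, cost2, allowed)
  if (ph2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  Tab <- ph2$Tab; basis <- ph2$basis
  x <- numeric(n)
  keep <- basis <= n
  x[basis[keep]] <- Tab[which(keep), N + 1]
  x[x < 0 & x > -eps] <- 0
  list(status = "optimal", x = x, value = sum(cvec * x))
}

#' Signed stoichiometric coefficients of one species across all reactions
#'
#' Works for internal and external species; the dot product with a flux
#' vector is the species' net production rate.
#'
#' @param network a \code{MetabolicNetwork}.
#' @param species species id.
#' @return numeric vector over the network's reactions.
#' @export
species_coeffs <- function(network, species) {
  out <- numeric(network$n_reactions)
  for (j in seq_len(network$n_reactions)) {
    st <- network$stoich[[j]]
    k <- match(species, st$ids)
    if (!is.na(k)) out[j] <- st$num[k] / st$den[k]
  }
  out
}

# carbon count of a species as a double; errors on unknown composition
.carbon_count <- function(network, species) {
  cc <- met_carbon(network, species)
  if (is.na(cc[["num"]]))
    stop(sprintf("species '%s' has no known carbon content", species),
         call. = FALSE)
  cc[["num"]] / cc[["den"]]
}

#' Maximum carbon yield by linear programming
#'
#' Fixes substrate uptake to 1, maximizes the secretion rate of the product
#' species over the steady-state flux cone and reports the carbon yield
#' \eqn{100 \cdot flux_p \cdot C_p / (flux_s \cdot C_s)}.  With
#' \code{require_biomass > 0} the optimum is the growth-coupled ceiling.
#'
#' @param network a \code{MetabolicNetwork}.
#' @param product external species id of the product (e.g. \code{"pdo_ext"},
#'   \code{"biomass_ext"}).
#' @param substrate external species id of the substrate (e.g.
#'   \code{"glc_ext"}).
#' @param require_biomass minimum biomass production rate (same scale as the
#'   unit substrate uptake), or zero for the unconstrained ceiling.
#' @param residual_tol verification tolerance on steady-state residuals of
#'   the returned vertex.
#' @return a \code{YieldResult} with \code{yield_percent}, the optimal flux
#'   vector over the original reactions and a status flag
#'   (\code{"optimal"} or \code{"infeasible"}).
#' @export
lp_max_yield <- function(network, product, substrate, require_biomass = 0,
                         residual_tol = 1e-9) {
  sp <- split_reversible(network)
  xnet <- sp$network
  S <- xnet$Snum / xnet$Sden
  n <- ncol(S)
  cons <- -species_coeffs(xnet, substrate)  # consumption is positive
  if (all(cons == 0))
    stop(sprintf("no reaction exchanges substrate '%s'", substrate),
         call. = FALSE)
  obj <- species_coeffs(xnet, product)
  A <- rbind(S, cons)
  b <- c(rep(0, nrow(S)), 1)
  if (require_biomass > 0) {
    # biomass production - slack = require_biomass
    bmrow <- species_coeffs(xnet, "biomass_ext")
    A <- rbind(cbind(A, 0), c(bmrow, -1))
    b <- c(b, require_biomass)
    obj <- c(obj, 0)
    n <- n + 1L
  }
  fit <- .simplex_two_phase(A, b, -obj)
  if (fit$status != "optimal")
    return(structure(list(product = product, substrate = substrate,
                          yield_percent = NA_real_, flux = NULL,
                          status = fit$status),
                     class = "YieldResult"))
  v <- fit$x[seq_len(xnet$n_reactions)]
  resid <- max(abs(A[, seq_len(xnet$n_reactions), drop = FALSE] %*% v -
                     b + if (require_biomass > 0) c(rep(0, length(b) - 1),
                                                    -fit$x[n]) else 0))
  if (resid > residual_tol * max(1, max(abs(v))))
    warning(sprintf("LP vertex residual %.2e exceeds tolerance", resid))
  cp <- .carbon_count(network, product)
  cs <- .carbon_count(network, substrate)
  yield <- 100 * sum(species_coeffs(xnet, product) * v) * cp / cs
  folded <- drop(fold_modes(matrix(v, nrow = 1), sp$mapping,
                            network$n_reactions))
  names(folded) <- network$rxns$id
  structure(list(product = product, substrate = substrate,
                 yield_percent = yield, flux = folded, status = "optimal"),
            class = "YieldResult")
}

#' @export
print.YieldResult <- function(x, ...) {
  cat(sprintf("YieldResult: %s from %s%s -> %s\n", x$product, x$substrate,
              if (!is.null(x$scenario)) paste0(" [", x$scenario, "]") else "",
              if (is.na(x$yield_percent)) x$status
              else sprintf("%.1f%% carbon yield", x$yield_percent)))
  invisible(x)
}
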