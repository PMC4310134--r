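# Random small stoichiometric networks with ground-truth elementary mode
# sets.  These fixtures exercise the enumeration engine and the yield
# analytics without the biological network: brute force over support subsets
# is exact for any network small enough to enumerate 2^n subsets.

#' Specification of a random test network
#'
#' @param n_internal_metabolites number of internal species.
#' @param n_reactions total reaction count (at most 14; the brute-force
#'   oracle enumerates all 2^n support subsets).
#' @param reversible_fraction fraction of non-exchange reactions drawn
#'   reversible.
#' @param max_abs_coefficient stoichiometric coefficients are drawn uniformly
#'   from \code{-max..-1, 1..max}.
#' @param seed integer seed; generation is a pure function of the spec.
#' @return a \code{RandomNetworkSpec}.
#' @export
random_network_spec <- function(n_internal_metabolites = 4, n_reactions = 8,
                                reversible_fraction = 0.3,
                                max_abs_coefficient = 3, seed = 0) {
  stopifnot(n_reactions <= 14, n_internal_metabolites >= 1,
            reversible_fraction >= 0, reversible_fraction <= 1,
            max_abs_coefficient >= 1)
  structure(list(n_internal_metabolites = n_internal_metabolites,
                 n_reactions = n_reactions,
                 reversible_fraction = reversible_fraction,
                 max_abs_coefficient = max_abs_coefficient,
                 seed = seed),
            class = "RandomNetworkSpec")
}

# run expr under a local Mersenne-Twister stream, restoring global RNG state
.with_local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

# reaction-metabolite incidence graph connectivity
.network_connected <- function(network) {
  n_m <- network$n_metabolites
  n_r <- network$n_reactions
  adj <- vector("list", n_m + n_r)
  for (j in seq_len(n_r)) {
    i <- match(network$stoich[[j]]$ids, network$mets$id)
    adj[[n_m + j]] <- i
    for (k in i) adj[[k]] <- c(adj[[k]], n_m + j)
  }
  seen <- logical(n_m + n_r)
  queue <- n_m + 1L
  seen[queue] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' Generate a random small network with exchanges
#'
#' Deterministic for a given spec: the same seed always yields the same
#' network.  The network always contains one uptake and one secretion
#' exchange; internal reactions are sparse random columns with small integer
#' coefficients, reversible with the requested probability.  Generation
#' retries until the reaction-metabolite graph is connected.
#'
#' @param spec a \code{RandomNetworkSpec} (or arguments passed on to
#'   \code{\link{random_network_spec}}).
#' @param max_tries retry budget for the connectivity requirement.
#' @return a \code{MetabolicNetwork}.
#' @export
random_network <- function(spec = random_network_spec(...), max_tries = 50, ...) {
  stopifnot(inherits(spec, "RandomNetworkSpec"))
  n_m <- spec$n_internal_metabolites
  n_r <- spec$n_reactions
  if (n_r < 3) stop("need at least uptake, one conversion and secretion",
                    call. = FALSE)
  .with_local_rng(spec$seed, {
    for (try in seq_len(max_tries)) {
      mets <- paste0("M", seq_len(n_m))
      lines <- c(sprintf("R1: S_ext -> %s | irrev | exchange", mets[1]),
                 sprintf("R%d: %s -> P_ext | irrev | exchange", n_r, mets[n_m]))
      internal_lines <- character(0)
      for (j in seq_len(n_r - 2L)) {
        n_sub <- sample(1:min(2, n_m), 1)
        subs <- sample(mets, n_sub)
        n_pro <- sample(1:min(2, n_m - 0), 1)
        pros <- sample(setdiff(mets, subs), min(n_pro, n_m - n_sub))
        if (!length(pros)) pros <- sample(setdiff(mets, subs[1]), 1)
        coef <- function(k) sample(seq_len(spec$max_abs_coefficient), k,
                                   replace = TRUE)
        lhs <- paste(paste(coef(length(subs)), subs), collapse = " + ")
        rhs <- paste(paste(coef(length(pros)), pros), collapse = " + ")
        rev <- stats::runif(1) < spec$reversible_fraction
        internal_lines <- c(internal_lines,
                            sprintf("R%d: %s -> %s | %s | core", j + 1L, lhs, rhs,
                                    if (rev) "rev" else "irrev"))
      }
      net <- parse_network(c(lines[1], internal_lines, lines[2]))
      if (.network_connected(net)) return(net)
    }
    stop("could not generate a connected network for this spec", call. = FALSE)
  })
}

#' Ground-truth elementary modes by exhaustive support enumeration
#'
#' Independent oracle for the enumeration engine: every support subset is
#' tested for a one-dimensional restricted nullspace whose generator has full
#' support on the subset and respects irreversibility.  Supports of
#' elementary modes form an antichain, so strict supersets of accepted
#' supports are pruned.
#'
#' @param network a \code{MetabolicNetwork} with at most 14 reactions.
#' @return an \code{efm_set} in the same canonical form as
#'   \code{\link{enumerate_efms}}.
#' @export
brute_force_efms <- function(network) {
  n <- network$n_reactions
  if (n > 14)
    stop("brute-force oracle limited to networks with <= 14 reactions",
         call. = FALSE)
  Sint <- stoich_int(network)
  m <- nrow(Sint)
  reversible <- network$rxns$reversible
  found <- list()
  found_supports <- matrix(FALSE, nrow = 0, ncol = n)
  for (size in seq_len(min(n, m + 1L))) {
    subsets <- utils::combn(n, size)
    for (ci in seq_len(ncol(subsets))) {
      T <- subsets[, ci]
      ind <- logical(n); ind[T] <- TRUE
      if (nrow(found_supports) &&
          any(rowSums(found_supports &
                      matrix(!ind, nrow(found_supports), n, byrow = TRUE)) == 0))
        next  # strict superset of an accepted support
      sub <- Sint[, T, drop = FALSE]
      ns <- rat_nullspace(sub, matrix(1, m, length(T)))
      if (ncol(ns) != 1L) next
      g <- ns[, 1]
      if (any(g == 0)) next  # generator lives on a smaller support
      irr <- !reversible[T]
      if (any(irr)) {
        s <- sign(g[irr])
        if (length(unique(s)) > 1L) next
        if (s[1] < 0) g <- -g
      } else if (g[1] < 0) g <- -g
      v <- numeric(n); v[T] <- g
      found[[length(found) + 1L]] <- v
      found_supports <- rbind(found_supports, ind)
    }
  }
  fluxes <- if (length(found)) do.call(rbind, found) else matrix(0, 0, n)
  fluxes <- .canonical_sign(fluxes, reversible)
  if (nrow(fluxes)) fluxes <- fluxes[.order_modes(fluxes), , drop = FALSE]
  colnames(fluxes) <- network$rxns$id
  structure(list(fluxes = fluxes, reaction_ids = network$rxns$id),
            class = "efm_set")
}
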