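# Elementary flux mode enumeration.
#
# Nullspace-free double description on the split irreversible network:
# reversible reactions become forward/backward columns, the candidate matrix
# starts as the identity over reaction space paired with the residual S^T
# block, and metabolite constraints are processed one at a time (cheapest
# first).  Rows already satisfying a constraint are kept; sign-opposite row
# pairs are combined, and a combination survives only if no other candidate's
# support is contained in the union of the pair's supports (combinatorial
# adjacency test).  All arithmetic is exact on integer-valued doubles.
#
# Before enumeration the network is compressed by the standard
# mode-preserving reductions: reactions forced to zero flux are removed and
# metabolites touched by exactly two reactions are eliminated by merging the
# pair into one lumped column.  A rational map from compressed to original
# reaction space folds every mode back afterwards.

# stoichiometric matrix with every row scaled to integers
stoich_int <- function(network) {
  Snum <- network$Snum; Sden <- network$Sden
  if (!nrow(Snum)) return(Snum)
  out <- Snum
  for (i in seq_len(nrow(Snum))) {
    lcm <- 1
    for (d in unique(Sden[i, ])) {
      .rat_guard(lcm, d)
      lcm <- lcm / gcd_int(lcm, d) * d
    }
    out[i, ] <- Snum[i, ] * (lcm / Sden[i, ])
  }
  out
}

#' Split reversible reactions into irreversible forward/backward pairs
#'
#' @param network a \code{MetabolicNetwork}.
#' @return list with the expanded all-irreversible network and a mapping table
#'   (\code{orig}, \code{dir}) used by \code{\link{fold_modes}} to fold flux
#'   vectors back into the original reaction space.
#' @export
split_reversible <- function(network) {
  n <- network$n_reactions
  rev <- which(network$rxns$reversible)
  orig <- c(seq_len(n), rev)
  dir <- c(rep(1, n), rep(-1, length(rev)))
  ids <- c(network$rxns$id,
           if (length(rev)) paste0(network$rxns$id[rev], "__rev") else character(0))
  stoich <- vector("list", length(orig))
  for (k in seq_along(orig)) {
    st <- network$stoich[[orig[k]]]
    if (dir[k] < 0) st$num <- -st$num
    stoich[[k]] <- st
  }
  expanded <- network
  expanded$rxns <- data.frame(id = ids, reversible = FALSE,
                              tag = network$rxns$tag[orig],
                              stringsAsFactors = FALSE)
  expanded$stoich <- stoich
  expanded$n_reactions <- length(orig)
  expanded <- rebuild_matrix(expanded)
  list(network = expanded,
       mapping = data.frame(col = seq_along(orig), orig = orig, dir = dir,
                            id = ids, stringsAsFactors = FALSE))
}

#' Fold split-network flux vectors back to the original reaction space
#'
#' @param fluxes matrix with one row per mode, columns = split reactions.
#' @param mapping the mapping returned by \code{\link{split_reversible}}.
#' @param n_orig number of reactions in the original network.
#' @return matrix with one row per mode over the original reactions.
#' @export
fold_modes <- function(fluxes, mapping, n_orig) {
  out <- matrix(0, nrow = nrow(fluxes), ncol = n_orig)
  for (k in seq_len(nrow(mapping)))
    out[, mapping$orig[k]] <- out[, mapping$orig[k]] +
      mapping$dir[k] * fluxes[, mapping$col[k]]
  out
}

# canonical sign: irreversible support positive; otherwise first nonzero > 0
.canonical_sign <- function(mat, reversible) {
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    nz <- which(v != 0)
    irr <- nz[!reversible[nz]]
    flip <- if (length(irr)) any(v[irr] < 0) else v[nz[1]] < 0
    if (flip) mat[i, ] <- -v
  }
  mat
}

# deterministic order: support size, then support pattern, then flux values
.order_modes <- function(mat) {
  supp <- mat != 0
  keys <- c(list(rowSums(supp)),
            lapply(seq_len(ncol(mat)), function(j) -supp[, j]),
            lapply(seq_len(ncol(mat)), function(j) mat[, j]))
  do.call(order, keys)
}

# --- mode-preserving compression ------------------------------------------
#
# Works on the rational stoichiometric matrix over internal metabolites.
# Returns the compressed matrix (rational), per-column reversibility, and an
# exact rational map M (original reactions x compressed columns) such that an
# original flux vector is M %*% v for a compressed mode v.
.compress_network <- function(Sn, Sd, rev) {
  n <- ncol(Sn)
  Mn <- diag(1, n); Md <- matrix(1, n, n)
  repeat {
    changed <- FALSE
    # enforced zeros: an all-irreversible row with one sign only, or a
    # metabolite touched by a single (even reversible) reaction
    repeat {
      drop <- logical(ncol(Sn)); hit <- FALSE
      for (i in seq_len(nrow(Sn))) {
        nz <- which(Sn[i, ] != 0)
        if (!length(nz)) next
        if (length(nz) == 1L) {
          if (!drop[nz]) { drop[nz] <- TRUE; hit <- TRUE }
        } else if (all(!rev[nz])) {
          s <- sign(Sn[i, nz])
          if (all(s > 0) || all(s < 0)) {
            if (!all(drop[nz])) { drop[nz] <- TRUE; hit <- TRUE }
          }
        }
      }
      if (!hit) break
      keep <- !drop
      Sn <- Sn[, keep, drop = FALSE]; Sd <- Sd[, keep, drop = FALSE]
      Mn <- Mn[, keep, drop = FALSE]; Md <- Md[, keep, drop = FALSE]
      rev <- rev[keep]; changed <- TRUE
      if (!ncol(Sn)) return(list(Sn = Sn, Sd = Sd, rev = rev, Mn = Mn, Md = Md))
      nzrow <- rowSums(Sn != 0) > 0
      Sn <- Sn[nzrow, , drop = FALSE]; Sd <- Sd[nzrow, , drop = FALSE]
    }
    # merge a metabolite touched by exactly two reactions
    for (i in seq_len(nrow(Sn))) {
      nz <- which(Sn[i, ] != 0)
      if (length(nz) != 2L) next
      j <- nz[1]; k <- nz[2]
      same_sign <- sign(Sn[i, j]) == sign(Sn[i, k])
      if (same_sign) {
        if (rev[k]) {
          # use the reverse orientation of k
        } else if (rev[j]) {
          tmp <- j; j <- k; k <- tmp
        } else next  # both irreversible, same sign: leave to other rules
        Sn[, k] <- -Sn[, k]; Mn[, k] <- -Mn[, k]
      }
      a_n <- abs(Sn[i, k]); a_d <- Sd[i, k]   # multiplier for column j
      b_n <- abs(Sn[i, j]); b_d <- Sd[i, j]   # multiplier for column k
      comb <- function(Xn, Xd) {
        t1 <- rat_mul(Xn[, j], Xd[, j], a_n, a_d)
        t2 <- rat_mul(Xn[, k], Xd[, k], b_n, b_d)
        rat_add(t1$num, t1$den, t2$num, t2$den)
      }
      sc <- comb(Sn, Sd); mc <- comb(Mn, Md)
      Sn[, j] <- sc$num; Sd[, j] <- sc$den
      Mn[, j] <- mc$num; Md[, j] <- mc$den
      rev[j] <- rev[j] && rev[k]
      keep <- setdiff(seq_len(ncol(Sn)), k)
      Sn <- Sn[, keep, drop = FALSE]; Sd <- Sd[, keep, drop = FALSE]
      Mn <- Mn[, keep, drop = FALSE]; Md <- Md[, keep, drop = FALSE]
      rev <- rev[keep]
      nzrow <- rowSums(Sn != 0) > 0
      Sn <- Sn[nzrow, , drop = FALSE]; Sd <- Sd[nzrow, , drop = FALSE]
      changed <- TRUE
      break
    }
    if (!changed) break
  }
  list(Sn = Sn, Sd = Sd, rev = rev, Mn = Mn, Md = Md)
}

# --- nullspace double description core -------------------------------------
#
# A: integer constraint matrix (metabolites x columns), all columns
# irreversible.  Start from a kernel basis in column-echelon form: with
# pivot coordinates p_1..p_d, the basis vectors b_i satisfy b_i[p_k] = δ_ik,
# so the cone {v in ker A : v_p >= 0 for all pivots p} is exactly the
# nonnegative hull of the basis.  The remaining nonnegativity constraints
# are then imposed one at a time by double description steps with the
# combinatorial adjacency test restricted to processed coordinates.
# Returns primitive integer generators (rows).
.dd_core <- function(A, max_rays, quiet = TRUE) {
  nn <- ncol(A)
  if (!nrow(A)) return(diag(1, nn))
  K <- rat_nullspace(A, matrix(1, nrow(A), ncol(A)))  # nn x d, integer
  d <- ncol(K)
  if (!d) return(matrix(0, 0, nn))
  # column-echelon: rref of t(K) gives basis rows with identity at pivots
  rr <- rat_rref(t(K), matrix(1, d, nn))
  pivots <- rr$pivots
  R <- matrix(0, nrow = d, ncol = nn)
  for (i in seq_len(d)) {
    lcm <- 1
    for (dd in unique(rr$den[i, ])) {
      .rat_guard(lcm, dd)
      lcm <- lcm / gcd_int(lcm, dd) * dd
    }
    R[i, ] <- int_primitive(rr$num[i, ] * (lcm / rr$den[i, ]))
    if (R[i, pivots[i]] < 0) R[i, ] <- -R[i, ]
  }
  remaining <- setdiff(seq_len(nn), pivots)
  out <- .dd_core_cpp(R, as.integer(pivots), as.integer(remaining),
                      max_rays, quiet)
  if (nrow(out) && max(abs(out)) >= 2^53)
    stop("elementary mode enumeration: exact integer range exceeded",
         call. = FALSE)
  out
}

#' Enumerate all elementary flux modes of a network
#'
#' Returns the complete set of elementary modes in the original reaction
#' space: primitive integer flux vectors with canonical sign, spurious
#' forward/backward two-cycles removed, in a deterministic order.
#'
#' @param network a \code{MetabolicNetwork}.
#' @param max_rays resource guard: abort if the intermediate candidate count
#'   exceeds this ceiling.
#' @param quiet suppress progress output.
#' @return an \code{efm_set}: list with \code{fluxes} (modes x reactions
#'   integer matrix, columns named by reaction id) and \code{reaction_ids}.
#' @export
enumerate_efms <- function(network, max_rays = 5e5, quiet = TRUE) {
  n_orig <- network$n_reactions
  empty <- function() {
    structure(list(fluxes = matrix(0, 0, n_orig,
                                   dimnames = list(NULL, network$rxns$id)),
                   reaction_ids = network$rxns$id),
              class = "efm_set")
  }
  if (!nrow(network$Snum) || !n_orig) return(empty())
  cp <- .compress_network(network$Snum, network$Sden, network$rxns$reversible)
  nc <- ncol(cp$Sn)
  if (!nc) return(empty())

  # integer constraint matrix via exact column scaling (flux unit change)
  split_orig <- c(seq_len(nc), which(cp$rev))
  split_dir <- c(rep(1, nc), rep(-1, sum(cp$rev)))
  A <- matrix(0, nrow = nrow(cp$Sn), ncol = length(split_orig))
  Dnum <- rep(1, length(split_orig))   # flux unit factor: v_orig = v * D
  Dden <- rep(1, length(split_orig))
  if (nrow(A)) {
    for (k in seq_along(split_orig)) {
      j <- split_orig[k]
      lcm <- 1
      for (d in unique(cp$Sd[, j])) {
        .rat_guard(lcm, d)
        lcm <- lcm / gcd_int(lcm, d) * d
      }
      colv <- cp$Sn[, j] * (lcm / cp$Sd[, j]) * split_dir[k]
      g <- max(gcd_vec(colv), 1)
      A[, k] <- colv / g               # primitive integer column
      dd <- rat_reduce(lcm, g)
      Dnum[k] <- dd$num; Dden[k] <- dd$den
    }
  }

  R <- .dd_core(A, max_rays, quiet)
  if (!nrow(R)) return(empty())

  # drop futile forward/backward two-cycles (support test is scale-free)
  two_cycle <- vapply(seq_len(nrow(R)), function(k) {
    s <- which(R[k, ] != 0)
    length(s) == 2L && split_orig[s[1]] == split_orig[s[2]]
  }, TRUE)
  R <- R[!two_cycle, , drop = FALSE]
  if (!nrow(R)) return(empty())

  # per mode: undo the column scaling, fold split -> compressed, and map to
  # the original reaction space, all in exact rationals, then clear
  # denominators to a primitive integer flux vector
  folded <- matrix(0, nrow = nrow(R), ncol = n_orig)
  for (r in seq_len(nrow(R))) {
    cn <- numeric(nc); cd <- rep(1, nc)
    for (k in which(R[r, ] != 0)) {
      j <- split_orig[k]
      t <- rat_mul(R[r, k] * split_dir[k], 1, Dnum[k], Dden[k])
      s <- rat_add(cn[j], cd[j], t$num, t$den)
      cn[j] <- s$num; cd[j] <- s$den
    }
    vn <- numeric(n_orig); vd <- rep(1, n_orig)
    for (j in which(cn != 0)) {
      t <- rat_mul(cp$Mn[, j], cp$Md[, j], cn[j], cd[j])
      s <- rat_add(vn, vd, t$num, t$den)
      vn <- s$num; vd <- s$den
    }
    lcm <- 1
    for (d in unique(vd)) {
      .rat_guard(lcm, d)
      lcm <- lcm / gcd_int(lcm, d) * d
    }
    folded[r, ] <- int_primitive(vn * (lcm / vd))
  }
  folded <- .canonical_sign(folded, network$rxns$reversible)
  folded <- unique(folded)
  folded <- folded[.order_modes(folded), , drop = FALSE]
  colnames(folded) <- network$rxns$id
  structure(list(fluxes = folded, reaction_ids = network$rxns$id),
            class = "efm_set")
}

#' @export
print.efm_set <- function(x, ...) {
  cat(sprintf("efm_set: %d elementary modes over %d reactions\n",
              nrow(x$fluxes), length(x$reaction_ids)))
  invisible(x)
}

#' Number of modes in an efm_set
#' @param modes an \code{efm_set}.
#' @export
n_modes <- function(modes) nrow(modes$fluxes)

#' Test whether a steady-state flux vector is an elementary mode
#'
#' A steady-state, sign-feasible flux vector is elementary iff the nullspace
#' of the stoichiometric matrix restricted to its support is one-dimensional.
#'
#' @param network a \code{MetabolicNetwork}.
#' @param flux integer-valued flux vector, named by reaction id or in network
#'   reaction order.
#' @return \code{TRUE} or \code{FALSE}; vectors violating steady state or
#'   irreversibility raise an error.
#' @export
is_elementary <- function(network, flux) {
  if (!is.null(names(flux))) {
    v <- numeric(network$n_reactions)
    i <- match(names(flux), network$rxns$id)
    if (anyNA(i)) stop("unknown reaction id in flux vector", call. = FALSE)
    v[i] <- flux
  } else {
    if (length(flux) != network$n_reactions)
      stop("flux vector length does not match network", call. = FALSE)
    v <- as.numeric(flux)
  }
  if (any(v != round(v)))
    stop("flux vector must be integer-valued (scale it first)", call. = FALSE)
  Sint <- stoich_int(network)
  if (nrow(Sint) && any(Sint %*% v != 0))
    stop("flux vector violates steady state (S v != 0)", call. = FALSE)
  if (any(!network$rxns$reversible & v < 0))
    stop("flux vector violates irreversibility", call. = FALSE)
  supp <- which(v != 0)
  if (!length(supp)) stop("zero flux vector is not a mode", call. = FALSE)
  sub <- Sint[, supp, drop = FALSE]
  ns <- rat_nullspace(sub, matrix(1, nrow(sub), ncol(sub)))
  ncol(ns) == 1L
}
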