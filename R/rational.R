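# Exact rational arithmetic on integer-valued doubles.
#
# Elementarity of a flux mode is a combinatorial property of exact linear
# algebra; floating-point tolerances corrupt it.  All stoichiometry and all
# nullspace/rank computations therefore run over rationals represented as
# parallel numerator/denominator vectors of integer-valued doubles.  Doubles
# are exact integers up to 2^53; operations guard their operands so that no
# intermediate product can silently lose exactness.

.RAT_MAX <- 2^52

# doubles hold integers exactly up to 2^53; any computed value at or beyond
# .RAT_MAX may already have lost exactness, so abort rather than continue
.rat_guard <- function(...) {
  m <- max(abs(c(...)), 0)
  if (m > .RAT_MAX)
    stop("rational overflow: intermediate value exceeds exact integer range",
         call. = FALSE)
  invisible(NULL)
}

# vectorized Euclid with recycling; gcd(0, 0) = 0
gcd_int <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(abs(a), n)
  b <- rep_len(abs(b), n)
  while (any(b > 0)) {
    r <- ifelse(b > 0, a %% b, a)
    a <- ifelse(b > 0, b, a)
    b <- ifelse(b > 0, r, 0)
  }
  a
}

gcd_vec <- function(x) {
  g <- 0
  for (v in abs(x)) {
    g <- gcd_int(g, v)
    if (g == 1) break
  }
  g
}

# reduce num/den pairs to canonical form (den > 0, gcd 1, 0 -> 0/1)
rat_reduce <- function(num, den) {
  if (any(den == 0)) stop("rational with zero denominator", call. = FALSE)
  neg <- den < 0
  num[neg] <- -num[neg]
  den[neg] <- -den[neg]
  g <- gcd_int(num, den)
  g[g == 0] <- 1
  num <- num / g
  den <- den / g
  den[num == 0] <- 1
  list(num = num, den = den)
}

rat_add <- function(n1, d1, n2, d2) {
  p1 <- n1 * d2; p2 <- n2 * d1; dd <- d1 * d2
  .rat_guard(p1, p2, dd, p1 + p2)
  rat_reduce(p1 + p2, dd)
}

rat_mul <- function(n1, d1, n2, d2) {
  # reduce crosswise first so the products stay as small as possible
  g1 <- gcd_int(abs(n1), d2); g1[g1 == 0] <- 1
  g2 <- gcd_int(abs(n2), d1); g2[g2 == 0] <- 1
  nn <- (n1 / g1) * (n2 / g2)
  dd <- (d1 / g2) * (d2 / g1)
  .rat_guard(nn, dd)
  rat_reduce(nn, dd)
}

rat_div <- function(n1, d1, n2, d2) {
  if (any(n2 == 0)) stop("rational division by zero", call. = FALSE)
  rat_mul(n1, d1, d2, n2)
}

# Parse one coefficient token: integer, finite decimal or "p/q".
# "0.33" is read as the exact rational 33/100, never as a float.
rat_parse <- function(token) {
  token <- trimws(token)
  if (grepl("^[+-]?[0-9]+$", token))
    return(rat_reduce(as.numeric(token), 1))
  if (grepl("^[+-]?[0-9]+/[0-9]+$", token)) {
    parts <- strsplit(token, "/", fixed = TRUE)[[1]]
    return(rat_reduce(as.numeric(parts[1]), as.numeric(parts[2])))
  }
  if (grepl("^[+-]?[0-9]*\\.[0-9]+$", token)) {
    sgn <- if (startsWith(token, "-")) -1 else 1
    token <- sub("^[+-]", "", token)
    parts <- strsplit(token, ".", fixed = TRUE)[[1]]
    whole <- if (nzchar(parts[1])) as.numeric(parts[1]) else 0
    frac <- parts[2]
    den <- 10^nchar(frac)
    return(rat_reduce(sgn * (whole * den + as.numeric(frac)), den))
  }
  stop(sprintf("malformed coefficient '%s'", token), call. = FALSE)
}

rat_format <- function(num, den) {
  ifelse(den == 1, format(num, scientific = FALSE, trim = TRUE),
         paste0(format(num, scientific = FALSE, trim = TRUE), "/",
                format(den, scientific = FALSE, trim = TRUE)))
}

# divide an integer vector by the gcd of its entries (primitive vector)
int_primitive <- function(x) {
  g <- gcd_vec(x)
  if (g > 1) x <- x / g
  x
}

# Exact reduced row echelon form of a rational matrix given as numerator and
# denominator matrices.  Returns the echelon form plus pivot columns.
rat_rref <- function(num, den) {
  num <- as.matrix(num); den <- as.matrix(den)
  m <- nrow(num); n <- ncol(num)
  pivots <- integer(0)
  r <- 1L
  for (j in seq_len(n)) {
    if (r > m) break
    # pick the structurally simplest nonzero pivot in rows r..m
    cand <- which(num[r:m, j] != 0) + r - 1L
    if (!length(cand)) next
    mag <- abs(num[cand, j]) * den[cand, j]
    p <- cand[which.min(mag)]
    if (p != r) {
      num[c(r, p), ] <- num[c(p, r), ]
      den[c(r, p), ] <- den[c(p, r), ]
    }
    # scale row r so that entry (r, j) = 1
    piv_n <- num[r, j]; piv_d <- den[r, j]
    sc <- rat_mul(num[r, ], den[r, ], piv_d, piv_n)
    num[r, ] <- sc$num; den[r, ] <- sc$den
    # eliminate column j from every other row
    for (i in seq_len(m)) {
      if (i == r || num[i, j] == 0) next
      f_n <- num[i, j]; f_d <- den[i, j]
      prod <- rat_mul(num[r, ], den[r, ], -f_n, f_d)
      s <- rat_add(num[i, ], den[i, ], prod$num, prod$den)
      num[i, ] <- s$num; den[i, ] <- s$den
    }
    pivots <- c(pivots, j)
    r <- r + 1L
  }
  list(num = num, den = den, pivots = pivots, rank = length(pivots))
}

rat_rank <- function(num, den) rat_rref(num, den)$rank

# Exact rational nullspace; returns an integer matrix whose columns are
# primitive basis vectors of the kernel (empty matrix for trivial kernel).
rat_nullspace <- function(num, den) {
  num <- as.matrix(num); den <- as.matrix(den)
  n <- ncol(num)
  rr <- rat_rref(num, den)
  free <- setdiff(seq_len(n), rr$pivots)
  basis <- matrix(0, nrow = n, ncol = length(free))
  if (!length(free)) return(basis)
  for (k in seq_along(free)) {
    f <- free[k]
    v_n <- numeric(n); v_d <- rep(1, n)
    v_n[f] <- 1
    if (length(rr$pivots)) {
      v_n[rr$pivots] <- -rr$num[seq_along(rr$pivots), f]
      v_d[rr$pivots] <- rr$den[seq_along(rr$pivots), f]
    }
    lcm <- 1
    for (d in unique(v_d)) {
      .rat_guard(lcm, d)
      lcm <- lcm / gcd_int(lcm, d) * d
    }
    basis[, k] <- int_primitive(v_n * (lcm / v_d))
  }
  basis
}
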