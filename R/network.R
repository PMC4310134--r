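# Stoichiometric network data model and the reaction-table dialect.
#
# A network is parsed from plain text, one reaction per line:
#
#     <id>: <equation> | <rev|irrev> | <tag>
#
# with "#" comments, "+"-separated terms, "->" separating substrates from
# products and coefficients written as integers, finite decimals or "p/q"
# fractions (all kept as exact rationals).  Metabolite ids ending in "_ext"
# denote external species: they are exchangeable with the environment and are
# excluded from the steady-state stoichiometric matrix.  Elemental
# compositions come from a sidecar table (id <TAB> formula).

MET_EXT_SUFFIX <- "_ext$"

is_external_id <- function(id) grepl(MET_EXT_SUFFIX, id)

# parse a chemical formula such as "C6H12O6" into element counts
parse_formula <- function(formula) {
  out <- c(C = 0, H = 0, O = 0, N = 0, S = 0, P = 0)
  if (is.na(formula) || !nzchar(formula)) return(out + NA_real_)
  rest <- formula
  while (nzchar(rest)) {
    m <- regmatches(rest, regexec("^([CHONSP])([0-9]*)", rest))[[1]]
    if (!length(m))
      stop(sprintf("malformed formula '%s'", formula), call. = FALSE)
    cnt <- if (nzchar(m[3])) as.numeric(m[3]) else 1
    out[m[2]] <- out[m[2]] + cnt
    rest <- substring(rest, nchar(m[1]) + 1L)
  }
  out
}

#' Read a metabolite composition sidecar table
#'
#' Two tab-separated columns: metabolite id and elemental formula
#' (e.g. \code{glc_ext  C6H12O6}).  Lines starting with \code{#} are ignored.
#'
#' @param path path to the sidecar file.
#' @return data frame with one row per metabolite and integer element counts.
#' @export
read_compositions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t]+")
  ids <- vapply(parts, `[`, "", 1L)
  formulas <- vapply(parts, `[`, "", 2L)
  counts <- t(vapply(formulas, parse_formula, numeric(6)))
  data.frame(id = ids, C = counts[, "C"], H = counts[, "H"], O = counts[, "O"],
             N = counts[, "N"], S = counts[, "S"], P = counts[, "P"],
             row.names = NULL, stringsAsFactors = FALSE)
}

.parse_side <- function(side, line_no) {
  side <- trimws(side)
  if (!nzchar(side)) return(list(ids = character(0), num = numeric(0), den = numeric(0)))
  if (grepl("^\\+|\\+$", side))
    stop(sprintf("line %d: dangling '+' in equation side '%s'", line_no, side),
         call. = FALSE)
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  ids <- character(0); num <- numeric(0); den <- numeric(0)
  for (term in terms) {
    m <- regmatches(term, regexec(
      "^(([0-9][0-9./]*)[ \t]+)?([A-Za-z_][A-Za-z0-9_]*)$", term))[[1]]
    if (!length(m))
      stop(sprintf("line %d: malformed equation term '%s'", line_no, term),
           call. = FALSE)
    coef <- if (nzchar(m[3])) rat_parse(m[3]) else list(num = 1, den = 1)
    ids <- c(ids, m[4]); num <- c(num, coef$num); den <- c(den, coef$den)
  }
  list(ids = ids, num = num, den = den)
}

.parse_reaction_line <- function(line, line_no) {
  m <- regmatches(line, regexec("^([A-Za-z0-9_]+)[ \t]*:(.*)$", line))[[1]]
  if (!length(m))
    stop(sprintf("line %d: malformed reaction line (missing '<id>:')", line_no),
         call. = FALSE)
  id <- m[2]
  fields <- trimws(strsplit(m[3], "|", fixed = TRUE)[[1]])
  if (length(fields) != 3L)
    stop(sprintf("line %d: expected '<id>: <eq> | <rev|irrev> | <tag>'", line_no),
         call. = FALSE)
  if (!fields[2] %in% c("rev", "irrev"))
    stop(sprintf("line %d: reversibility flag must be 'rev' or 'irrev'", line_no),
         call. = FALSE)
  tags <- c("core", "exchange", "product_pathway", "eet", "biomass")
  if (!fields[3] %in% tags)
    stop(sprintf("line %d: unknown tag '%s'", line_no, fields[3]), call. = FALSE)
  # pad so that an empty product side (pure drain) survives strsplit
  sides <- strsplit(paste0(fields[1], " "), "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop(sprintf("line %d: equation must contain exactly one '->'", line_no),
         call. = FALSE)
  lhs <- .parse_side(sides[1], line_no)
  rhs <- .parse_side(sides[2], line_no)
  ids <- c(lhs$ids, rhs$ids)
  num <- c(-lhs$num, rhs$num)
  den <- c(lhs$den, rhs$den)
  if (!length(ids))
    stop(sprintf("line %d: reaction '%s' has no metabolites", line_no, id),
         call. = FALSE)
  # merge repeated species (e.g. catalytic appearances on both sides)
  uids <- unique(ids)
  unum <- numeric(length(uids)); uden <- rep(1, length(uids))
  for (k in seq_along(ids)) {
    i <- match(ids[k], uids)
    s <- rat_add(unum[i], uden[i], num[k], den[k])
    unum[i] <- s$num; uden[i] <- s$den
  }
  keep <- unum != 0
  if (!any(keep))
    stop(sprintf("line %d: reaction '%s' has all-zero stoichiometry", line_no, id),
         call. = FALSE)
  list(id = id, reversible = fields[2] == "rev", tag = fields[3],
       ids = uids[keep], num = unum[keep], den = uden[keep])
}

#' Parse a reaction table into a metabolic network
#'
#' @param text character vector of reaction-table lines, or a single string
#'   naming a file when \code{is_file} is \code{TRUE}.
#' @param compositions optional composition data frame from
#'   \code{\link{read_compositions}}.
#' @param is_file read \code{text} from disk first.
#' @return a \code{MetabolicNetwork}: metabolite table, reaction table and the
#'   exact rational stoichiometric matrix over internal metabolites.
#' @examples
#' net <- parse_network(c("R_up: glc_ext -> glc | irrev | exchange",
#'                        "R_out: glc -> co2_ext | irrev | core"))
#' net$n_reactions
#' @export
parse_network <- function(text, compositions = NULL, is_file = FALSE) {
  if (is_file) text <- readLines(text, warn = FALSE)
  raw <- trimws(sub("#.*$", "", text))
  line_nos <- which(nzchar(raw))
  rxns <- lapply(line_nos, function(i) .parse_reaction_line(raw[i], i))
  ids <- vapply(rxns, `[[`, "", "id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate reaction id(s): %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  met_ids <- unique(unlist(lapply(rxns, `[[`, "ids")))
  external <- is_external_id(met_ids)
  mets <- data.frame(id = met_ids, external = external,
                     C = NA_real_, C_den = 1, H = NA_real_, O = NA_real_,
                     N = NA_real_, S = NA_real_, P = NA_real_,
                     stringsAsFactors = FALSE)
  net <- structure(list(mets = mets,
                        rxns = data.frame(
                          id = ids,
                          reversible = vapply(rxns, `[[`, TRUE, "reversible"),
                          tag = vapply(rxns, `[[`, "", "tag"),
                          stringsAsFactors = FALSE),
                        stoich = lapply(rxns, function(r) r[c("ids", "num", "den")]),
                        n_metabolites = nrow(mets),
                        n_reactions = length(ids)),
                   class = "MetabolicNetwork")
  if (!is.null(compositions)) net <- set_compositions(net, compositions)
  rebuild_matrix(net)
}

#' @rdname parse_network
#' @param network a \code{MetabolicNetwork}.
#' @export
set_compositions <- function(network, compositions) {
  i <- match(network$mets$id, compositions$id)
  hit <- !is.na(i)
  for (el in c("C", "H", "O", "N", "S", "P"))
    network$mets[[el]][hit] <- compositions[[el]][i[hit]]
  network$mets$C_den[hit] <- 1
  rebuild_matrix(network)
}

# assemble the stoichiometric matrix over internal metabolites
rebuild_matrix <- function(network) {
  internal <- network$mets$id[!network$mets$external]
  n <- network$n_reactions
  Snum <- matrix(0, nrow = length(internal), ncol = n,
                 dimnames = list(internal, network$rxns$id))
  Sden <- matrix(1, nrow = length(internal), ncol = n,
                 dimnames = list(internal, network$rxns$id))
  for (j in seq_len(n)) {
    st <- network$stoich[[j]]
    k <- match(st$ids, internal)
    keep <- !is.na(k)
    Snum[k[keep], j] <- st$num[keep]
    Sden[k[keep], j] <- st$den[keep]
  }
  network$Snum <- Snum
  network$Sden <- Sden
  network$n_metabolites <- nrow(network$mets)
  network$n_reactions <- n
  network
}

#' Serialize a network back to the reaction-table dialect
#'
#' \code{parse_network(format_network(net))} reproduces the stoichiometric
#' matrix entry for entry.
#'
#' @param network a \code{MetabolicNetwork}.
#' @return character vector of reaction-table lines.
#' @export
format_network <- function(network) {
  vapply(seq_len(network$n_reactions), function(j) {
    st <- network$stoich[[j]]
    fmt_side <- function(sel) {
      if (!any(sel)) return("")
      paste(ifelse(abs(st$num[sel]) == 1 & st$den[sel] == 1, st$ids[sel],
                   paste(rat_format(abs(st$num[sel]), st$den[sel]), st$ids[sel])),
            collapse = " + ")
    }
    sprintf("%s: %s -> %s | %s | %s", network$rxns$id[j],
            fmt_side(st$num < 0), fmt_side(st$num > 0),
            if (network$rxns$reversible[j]) "rev" else "irrev",
            network$rxns$tag[j])
  }, "")
}

#' @export
print.MetabolicNetwork <- function(x, ...) {
  cat(sprintf("MetabolicNetwork: %d metabolites (%d internal), %d reactions (%d reversible)\n",
              x$n_metabolites, sum(!x$mets$external), x$n_reactions,
              sum(x$rxns$reversible)))
  tab <- table(x$rxns$tag)
  cat("  reactions by tag:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  invisible(x)
}

# exact per-reaction balance of one element; NA if any composition unknown
.element_balance <- function(network, j, element) {
  st <- network$stoich[[j]]
  i <- match(st$ids, network$mets$id)
  counts <- network$mets[[element]][i]
  cden <- if (element == "C") network$mets$C_den[i] else rep(1, length(i))
  if (anyNA(counts)) return(NULL)
  bn <- 0; bd <- 1
  for (k in seq_along(i)) {
    term <- rat_mul(st$num[k], st$den[k], counts[k], cden[k])
    s <- rat_add(bn, bd, term$num, term$den)
    bn <- s$num; bd <- s$den
  }
  c(num = bn, den = bd)
}

#' Structural validation of a network
#'
#' Checks exact elemental balances of all core and product-pathway reactions
#' whose species all have known composition (exchange, EET and biomass
#' reactions are exempt by construction), and reports orphan metabolites and
#' dead-end metabolites whose reactions are forced to zero flux at steady
#' state.
#'
#' @param network a \code{MetabolicNetwork}.
#' @return a \code{network_validation} report; \code{$ok} is \code{TRUE} when
#'   no balanced-by-contract reaction has a carbon residual.
#' @export
validate_network <- function(network) {
  balance_tags <- c("core", "product_pathway")
  res <- lapply(seq_len(network$n_reactions), function(j) {
    if (!network$rxns$tag[j] %in% balance_tags)
      return(list(id = network$rxns$id[j], status = "exempt"))
    bal <- lapply(c("C", "H", "O", "N", "S", "P"),
                  function(el) .element_balance(network, j, el))
    names(bal) <- c("C", "H", "O", "N", "S", "P")
    if (is.null(bal$C))
      return(list(id = network$rxns$id[j], status = "unknown_composition"))
    list(id = network$rxns$id[j],
         status = if (bal$C[["num"]] == 0) "balanced" else "carbon_imbalance",
         carbon_residual = bal$C[["num"]] / bal$C[["den"]])
  })
  status <- vapply(res, `[[`, "", "status")
  used <- unique(unlist(lapply(network$stoich, `[[`, "ids")))
  orphans <- setdiff(network$mets$id, used)
  # dead-end internal metabolites: only ever produced or only ever consumed
  # by irreversible reactions
  internal <- rownames(network$Snum)
  dead <- character(0)
  for (i in seq_along(internal)) {
    row <- network$Snum[i, ]
    nz <- which(row != 0)
    rev_touch <- any(network$rxns$reversible[nz])
    if (!rev_touch && length(nz) &&
        (all(row[nz] > 0) || all(row[nz] < 0)))
      dead <- c(dead, internal[i])
  }
  structure(list(reactions = res,
                 carbon_imbalanced = vapply(res, `[[`, "", "id")[status == "carbon_imbalance"],
                 exempt = vapply(res, `[[`, "", "id")[status == "exempt"],
                 orphan_metabolites = orphans,
                 dead_end_metabolites = dead,
                 ok = !any(status == "carbon_imbalance")),
            class = "network_validation")
}

#' @export
print.network_validation <- function(x, ...) {
  cat(sprintf("network validation: %s\n", if (x$ok) "PASS" else "FAIL"))
  if (length(x$carbon_imbalanced))
    cat("  carbon-imbalanced:", paste(x$carbon_imbalanced, collapse = ", "), "\n")
  if (length(x$orphan_metabolites))
    cat("  orphan metabolites:", paste(x$orphan_metabolites, collapse = ", "), "\n")
  if (length(x$dead_end_metabolites))
    cat("  dead-end metabolites:", paste(x$dead_end_metabolites, collapse = ", "), "\n")
  invisible(x)
}

#' Carbon content of a species as an exact rational
#'
#' @param network a \code{MetabolicNetwork}.
#' @param met_id species id.
#' @return named vector \code{c(num, den)}; \code{num} is \code{NA} when the
#'   composition is unknown.
#' @export
met_carbon <- function(network, met_id) {
  i <- match(met_id, network$mets$id)
  if (is.na(i)) stop(sprintf("unknown metabolite '%s'", met_id), call. = FALSE)
  c(num = network$mets$C[i], den = network$mets$C_den[i])
}
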