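# Anaerobic E. coli core model construction.
#
# The packaged network covers glycolysis, glycerol degradation, the
# Entner-Doudoroff and pentose phosphate pathways, the TCA cycle with
# glyoxylate shunt and anaplerosis, anaerobic fermentation branches, the
# electron transport chain with proton-explicit energy conservation, both
# transhydrogenases and the biomass equation.  Production pathways for the
# twenty screened products are condensed to single lumped steps (documented
# per product below) and appended on demand, as are the electrode
# pseudo-reactions of an EET scenario and the aerobic respiration module.

.SUBSTRATE_SPECIES <- c(glucose = "glc_ext", glycerol = "glyc_ext",
                        fumarate = "fum_ext")
.SUBSTRATE_UPTAKE <- c(glucose = "R2", glycerol = "R64", fumarate = "R66")

# Condensed production pathways.  Each lump is derived from the standard
# (engineered) route; cofactor stoichiometry follows the electron and ~P
# bookkeeping of that route, carbon is balanced exactly.
#   1,3-PDO   G3P phosphatase, then glycerol dehydratase + NADH reductase
#             (from glucose the G3P step itself consumes one further NADH).
#   1,2-PDO   native methylglyoxal route of the main network (R17).
#   3-HP      glycerol dehydratase then NAD-linked aldehyde oxidation.
#   PA        succinate decarboxylation (methylmalonyl-CoA route, CoA
#             transfer conserved).
#   butyrate  reverse beta-oxidation from 2 acetyl-CoA, 2 NADH, thioesterase.
#   adipate   3-oxoadipyl-CoA route from succinyl-CoA + acetyl-CoA, 2 NADH.
#   lysine    aspartate pathway: OAA + pyruvate, 1 ATP, 4 NADPH, 1 CO2 out.
#   DAP       lysine decarboxylation (one further CO2).
#   isoprene  MEP pathway from pyruvate + GAP: 3 NADPH-equivalent
#             reductions, 2 ~P, 1 CO2 out.
#   2,3-BDO   acetolactate -> acetoin -> butanediol: 2 pyruvate, two
#             decarboxylations, net 1 NADH.
#   1,4-BDO   succinyl-CoA -> succinate semialdehyde -> 4-hydroxybutyrate
#             -> 1,4-BDO: 4 NAD(P)H reductions.
#   GABA      glutamate decarboxylation (NADPH amination of 2-oxoglutarate).
#   malate    direct export of the TCA intermediate.
#   aspartate OAA amination (glutamate-coupled, NADPH).
#   propanol  propionyl-CoA route from succinate, two NADH reductions.
#   pABA/pHBA shikimate pathway: 2 PEP + E4P, 1 NADPH, 1 ATP (pHBA) or
#             2 ATP (pABA, glutamine amide donor); chorismate lyase
#             releases pyruvate.
#   butanol   clostridial route from 2 acetyl-CoA, 4 NADH.
#   ethanol, succinate: native, no appended pathway.
.PRODUCTS <- list(
  "1,3-PDO" = list(species = "pdo_ext", lines = c(
    "P_pdo1: g3p -> glyc | irrev | product_pathway",
    "P_pdo2: glyc + nadh -> pdo_ext + nad | irrev | product_pathway")),
  "1,2-PDO" = list(species = "pdo12_ext", lines = character(0)),
  "3-HP" = list(species = "hp3_ext", lines = c(
    "P_hp1: g3p -> glyc | irrev | product_pathway",
    "P_hp2: glyc + nad -> hp3_ext + nadh | irrev | product_pathway")),
  "propionic acid" = list(species = "pa_ext", lines =
    "P_pa: succ -> pa_ext + co2 | irrev | product_pathway"),
  "butyric acid" = list(species = "but_ext", lines =
    "P_but: 2 accoa + 2 nadh -> but_ext + 2 nad | irrev | product_pathway"),
  "adipic acid" = list(species = "adp6_ext", lines =
    "P_adp6: succoa + accoa + 2 nadh -> adp6_ext + 2 nad | irrev | product_pathway"),
  "lysine" = list(species = "lys_ext", lines =
    "P_lys: oaa + pyr + atp + 4 nadph -> lys_ext + co2 + adp + 4 nadp | irrev | product_pathway"),
  "diaminopentane" = list(species = "dap_ext", lines =
    "P_dap: oaa + pyr + atp + 4 nadph -> dap_ext + 2 co2 + adp + 4 nadp | irrev | product_pathway"),
  "isoprene" = list(species = "iprn_ext", lines =
    "P_iprn: pyr + gap + 2 atp + 3 nadph -> iprn_ext + co2 + 2 adp + 3 nadp | irrev | product_pathway"),
  "2,3-BDO" = list(species = "bdo23_ext", lines =
    "P_bdo23: 2 pyr + nadh -> bdo23_ext + 2 co2 + nad | irrev | product_pathway"),
  "1,4-BDO" = list(species = "bdo14_ext", lines =
    "P_bdo14: succoa + 4 nadh -> bdo14_ext + 4 nad | irrev | product_pathway"),
  "GABA" = list(species = "gaba_ext", lines =
    "P_gaba: akg + nadph -> gaba_ext + co2 + nadp | irrev | product_pathway"),
  "malate" = list(species = "mal_ext", lines =
    "P_mal: mal -> mal_ext | irrev | exchange"),
  "aspartate" = list(species = "asp_ext", lines =
    "P_asp: oaa + nadph -> asp_ext + nadp | irrev | product_pathway"),
  "propanol" = list(species = "poh_ext", lines =
    "P_poh: succ + 2 nadh -> poh_ext + co2 + 2 nad | irrev | product_pathway"),
  "pABA" = list(species = "paba_ext", lines =
    "P_paba: 2 pep + e4p + 2 atp + nadph -> paba_ext + pyr + 2 adp + nadp | irrev | product_pathway"),
  "pHBA" = list(species = "phba_ext", lines =
    "P_phba: 2 pep + e4p + atp + nadph -> phba_ext + pyr + adp + nadp | irrev | product_pathway"),
  "ethanol" = list(species = "etoh_ext", lines = character(0)),
  "butanol" = list(species = "btoh_ext", lines =
    "P_btoh: 2 accoa + 4 nadh -> btoh_ext + 4 nad | irrev | product_pathway"),
  "succinate" = list(species = "succ_ext", lines = character(0)))

#' Products available to the screen
#'
#' @return character vector of the twenty screened product names.
#' @export
list_products <- function() names(.PRODUCTS)

.core_file <- function(name)
  system.file("extdata", name, package = "efmscreen", mustWork = TRUE)

#' Load the packaged core network (no substrate selection, all uptakes)
#'
#' @return the raw parsed 57-species, 75-reaction network.
#' @export
load_core_network <- function() {
  parse_network(.core_file("ecoli_core.txt"),
                compositions = read_compositions(.core_file("compositions.tsv")),
                is_file = TRUE)
}

#' Build the anaerobic core model for one screening cell
#'
#' Returns the core network with exactly one substrate uptake enabled, the
#' condensed pathway of the selected product appended, the electrode
#' pseudo-reactions of the EET scenario appended, and (only when
#' \code{aerobic}) an oxygen exchange plus proton-pumping terminal oxidase.
#' Anaerobiosis is the default and a technical requirement of cathodic
#' operation: \code{aerobic = TRUE} with a cathodic scenario is rejected.
#'
#' @param substrate \code{"glucose"}, \code{"glycerol"} or \code{"fumarate"}.
#' @param product one of \code{\link{list_products}()}, or \code{"none"}.
#' @param scenario an \code{\link{eet_scenario}} or scenario id string.
#' @param aerobic enable oxygen exchange and respiration.
#' @param aerobic_pumping protons pumped per quinol oxidised by the terminal
#'   oxidase (aerobic only).
#' @param biomass_atp optional override of the ATP demand (mmol per biomass
#'   unit) of the biomass equation.
#' @return a \code{MetabolicNetwork} with attributes \code{substrate_species},
#'   \code{product_species}, \code{product_name} and \code{scenario_id}.
#' @examples
#' net <- build_core_model("glucose", "1,3-PDO", "Cat1")
#' net
#' @export
build_core_model <- function(substrate = c("glucose", "glycerol", "fumarate"),
                             product = "none", scenario = "none",
                             aerobic = FALSE, aerobic_pumping = "5/2",
                             biomass_atp = NULL) {
  substrate <- match.arg(substrate)
  if (is.character(scenario)) scenario <- eet_scenario(scenario)
  if (is.null(product)) product <- "none"
  if (!identical(product, "none") && !product %in% names(.PRODUCTS))
    stop(sprintf("unknown product '%s'; see list_products()", product),
         call. = FALSE)
  if (aerobic && scenario$electrode_side == "cathode")
    stop("aerobic operation is incompatible with a cathodic scenario",
         call. = FALSE)
  lines <- readLines(.core_file("ecoli_core.txt"), warn = FALSE)
  drop_ids <- setdiff(.SUBSTRATE_UPTAKE, .SUBSTRATE_UPTAKE[[substrate]])
  lines <- lines[!grepl(sprintf("^(%s):", paste(drop_ids, collapse = "|")),
                        lines)]
  if (!identical(product, "none"))
    lines <- c(lines, .PRODUCTS[[product]]$lines)
  lines <- c(lines, scenario_reactions(scenario))
  if (aerobic) {
    pump <- .rat_approx(aerobic_pumping)
    lines <- c(lines,
               "R_o2: o2_ext -> o2 | irrev | exchange",
               sprintf("R_cyo: qh2 + 1/2 o2 -> q + %s hpp | irrev | core",
                       rat_format(pump$num, pump$den)))
  }
  net <- parse_network(lines,
                       compositions = read_compositions(.core_file("compositions.tsv")))
  if (!is.null(biomass_atp)) {
    coef <- .rat_approx(biomass_atp)
    j <- match("R1", net$rxns$id)
    st <- net$stoich[[j]]
    st$num[match("atp", st$ids)] <- -coef$num
    st$den[match("atp", st$ids)] <- coef$den
    st$num[match("adp", st$ids)] <- coef$num
    st$den[match("adp", st$ids)] <- coef$den
    net$stoich[[j]] <- st
    net <- rebuild_matrix(net)
  }
  net$substrate <- substrate
  net$substrate_species <- .SUBSTRATE_SPECIES[[substrate]]
  net$product_name <- product
  net$product_species <- if (identical(product, "none")) NA_character_
                         else .PRODUCTS[[product]]$species
  net$scenario_id <- scenario$id
  net
}
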