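# Electrode electron-transfer scenarios.
#
# Electrons are an external pseudo-species (e_ext) exchanged with the
# electrode without bound; the soluble mediator redox cycle is collapsed into
# that exchange.  Electrons move in pairs (one redox carrier per 2 e-).
# Energy coupling is mechanistic: proton-translocating transfers deposit
# protons into the periplasmic pool (hpp, an internal balanced species) and
# the ATP synthase of the core network conserves them at protons_per_atp
# (default 3) protons per ATP.
#
#   Cat1  cathodic, ATP-coupled: mediator oxidation on outer-membrane
#         cytochromes reduces NAD+; charge imbalance drives
#         protons_per_electron (default 1) protons per electron into the
#         cytosol through the ATP synthase, i.e. 2/3 ATP per NADH at the
#         defaults.
#   Cat2  cathodic, uncoupled: electrons and protons reduce NAD+ directly
#         (hydrogenase-like or mediator diffusion), no proton motive force.
#   An1   anodic, ATP-coupled: the mediator is reduced from the quinol pool
#         by membrane-bound cytochromes.  NADH electrons reach the anode
#         through the proton-pumping NADH dehydrogenase of the core network
#         (2 protons per electron), so ATP coupling arises from the chain
#         itself; anode_pumping adds any further protons per electron pumped
#         at the quinol-oxidising step (default 0).
#   An2   anodic, uncoupled: the anode drains electrons from NADH directly,
#         no membrane potential.

# best small-denominator rational approximation of a numeric
.rat_approx <- function(x, max_den = 1000) {
  if (is.character(x)) return(rat_parse(x))
  for (d in seq_len(max_den)) {
    n <- round(x * d)
    if (abs(x - n / d) < 1e-12) return(rat_reduce(n, d))
  }
  stop("parameter is not a small rational", call. = FALSE)
}

#' Construct an electrode electron-transfer scenario
#'
#' @param id one of \code{"none"}, \code{"Cat1"}, \code{"Cat2"},
#'   \code{"An1"}, \code{"An2"}.
#' @param protons_per_electron protons entering the cytosol per cathodic
#'   electron under Cat1 (charge balance influx); default 1.
#' @param protons_per_atp ATP synthase stoichiometry; default 3.
#' @param an1_pumping additional protons pumped per electron at the
#'   quinol-oxidising mediator step under An1 (on top of the proton-pumping
#'   NADH dehydrogenase of the core network); default 0.  Numerics or
#'   \code{"p/q"} strings are accepted and kept as exact rationals.
#' @return an \code{EETScenario}.
#' @export
eet_scenario <- function(id = c("none", "Cat1", "Cat2", "An1", "An2"),
                         protons_per_electron = 1, protons_per_atp = 3,
                         an1_pumping = 0) {
  id <- match.arg(id)
  ppe <- .rat_approx(protons_per_electron)
  ppa <- .rat_approx(protons_per_atp)
  pump <- .rat_approx(an1_pumping)
  if (ppe$num < 0 || ppa$num <= 0 || pump$num < 0)
    stop("EET coupling parameters must be non-negative (protons_per_atp > 0)",
         call. = FALSE)
  structure(list(id = id,
                 electrode_side = switch(id, none = "none",
                                         Cat1 = , Cat2 = "cathode",
                                         An1 = , An2 = "anode"),
                 atp_coupled = id %in% c("Cat1", "An1"),
                 protons_per_electron = ppe,
                 protons_per_atp = ppa,
                 anode_pumping_protons_per_electron = pump),
            class = "EETScenario")
}

#' @export
print.EETScenario <- function(x, ...) {
  cat(sprintf("EETScenario %s (%s%s)\n", x$id, x$electrode_side,
              if (x$atp_coupled) ", ATP-coupled" else ""))
  invisible(x)
}

#' Electrode pseudo-reactions of a scenario
#'
#' Returns the reaction-table lines (tag \code{eet}) appended to a network to
#' realise a scenario.  Electrons are exchanged in pairs: one NAD(H) redox
#' event per two electrode electrons.  Proton-coupled transfers deposit
#' protons into the periplasmic pool, where the ATP synthase conserves them.
#'
#' @param scenario an \code{EETScenario} (or a scenario id string).
#' @return character vector of reaction-table lines (empty for
#'   \code{"none"}).
#' @export
scenario_reactions <- function(scenario) {
  if (is.character(scenario)) scenario <- eet_scenario(scenario)
  stopifnot(inherits(scenario, "EETScenario"))
  fmt <- function(num, den) rat_format(num, den)
  switch(scenario$id,
    none = character(0),
    Cat1 = {
      h <- rat_mul(2, 1, scenario$protons_per_electron$num,
                   scenario$protons_per_electron$den)
      if (h$num == 0)
        "R_eet: 2 e_ext + nad -> nadh | irrev | eet"
      else
        sprintf("R_eet: 2 e_ext + nad -> nadh + %s hpp | irrev | eet",
                fmt(h$num, h$den))
    },
    Cat2 = "R_eet: 2 e_ext + nad -> nadh | irrev | eet",
    An1 = {
      h <- rat_mul(2, 1, scenario$anode_pumping_protons_per_electron$num,
                   scenario$anode_pumping_protons_per_electron$den)
      if (h$num == 0)
        "R_eet: qh2 -> q + 2 e_ext | irrev | eet"
      else
        sprintf("R_eet: qh2 -> q + 2 e_ext + %s hpp | irrev | eet",
                fmt(h$num, h$den))
    },
    An2 = "R_eet: nadh -> nad + 2 e_ext | irrev | eet")
}

#' Calibrate the free EET energy-coupling parameters against anchor yields
#'
#' The proton-pumping stoichiometry of the anodic chain (An1) and the
#' aerobic oxidase pumping ratio are not fixed by mechanism; they are chosen
#' by grid search over small rationals (denominators up to \code{max_den})
#' to minimise the worst absolute deviation of LP maximum biomass yields
#' from the supplied anchors.
#'
#' @param network_builder function \code{(scenario, substrate, aerobic)}
#'   returning a \code{MetabolicNetwork}; typically a thin wrapper around
#'   \code{\link{build_core_model}}.
#' @param targets list of anchor entries, each a list with \code{scenario}
#'   (id string or \code{"aerobic"}), \code{substrate} species id and
#'   \code{yield} (percent).
#' @param pump_grid candidate An1 pumping ratios (protons per electron).
#' @param max_den denominator bound for the default grid.
#' @param tol_pp acceptable worst-case deviation in percentage points.
#' @return list with the selected \code{an1_pumping}, \code{aerobic_pumping}
#'   (protons pumped per NADH oxidised aerobically), the achieved deviations
#'   and \code{within_tolerance}.
#' @export
calibrate_energetics <- function(network_builder, targets,
                                 pump_grid = NULL, max_den = 6, tol_pp = 1) {
  if (!length(targets))
    return(list(an1_pumping = 0, aerobic_pumping = 4, deviations = numeric(0),
                within_tolerance = TRUE))
  if (is.null(pump_grid)) {
    pump_grid <- unique(unlist(lapply(seq_len(max_den), function(d)
      (0:(4 * d)) / d)))
    pump_grid <- sort(pump_grid[pump_grid <= 4])
  }
  eval_anchor <- function(t, pump, aer) {
    aerobic <- identical(t$scenario, "aerobic")
    scen <- if (aerobic) eet_scenario("none")
            else eet_scenario(t$scenario, an1_pumping = pump)
    net <- network_builder(scen, t$substrate, aerobic = aerobic,
                           aerobic_pumping = aer)
    ssp <- if (!is.null(net$substrate_species)) net$substrate_species
           else t$substrate
    res <- lp_max_yield(net, "biomass_ext", ssp)
    res$yield_percent
  }
  needs_an1 <- any(vapply(targets, function(t) identical(t$scenario, "An1"), TRUE))
  needs_aer <- any(vapply(targets, function(t) identical(t$scenario, "aerobic"), TRUE))
  pump_cand <- if (needs_an1) pump_grid else 2
  aer_cand <- if (needs_aer) pump_grid else 4
  best <- NULL
  for (pump in pump_cand) {
    for (aer in aer_cand) {
      dev <- vapply(targets, function(t)
        abs(eval_anchor(t, pump, aer) - t$yield), 0)
      worst <- max(dev)
      if (is.null(best) || worst < best$worst)
        best <- list(an1_pumping = pump, aerobic_pumping = aer,
                     deviations = dev, worst = worst)
    }
  }
  list(an1_pumping = best$an1_pumping, aerobic_pumping = best$aerobic_pumping,
       deviations = best$deviations,
       within_tolerance = best$worst <= tol_pp)
}
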