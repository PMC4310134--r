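---
title: "Screening electro-fermentation by elementary mode analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening electro-fermentation by elementary mode analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efmscreen)
```

## The question the package answers

Electro-fermentation couples a fermenting microbe to an electrode, either
supplying electrons (a cathode) or draining them (an anode), usually through
a soluble redox mediator.  The promise is simple: many fermentation products
are more reduced or more oxidised than the substrate, so shifting the
cellular NADH/NAD+ balance electrically should lift yield ceilings that
redox balance otherwise imposes.  Whether a particular substrate-product
pair actually benefits, and by how much, is a purely stoichiometric question
that can be answered before any electrochemistry is attempted.  This package
answers it for an anaerobic *Escherichia coli* core network and twenty
industrially relevant products, by elementary flux mode (EFM) analysis with
a linear-programming (LP) cross-check.

## The model

The packaged network (`load_core_network()`) has 57 species and 75 reactions
(24 reversible): EMP glycolysis with the PTS glucose uptake, glycerol
degradation, the Entner-Doudoroff route (lumped to one step), the pentose
phosphate pathway, the TCA cycle with a lumped glyoxylate shunt and the
anaplerotic reactions, the anaerobic fermentation branches (lactate,
acetate, ethanol, formate/H2, succinate, the native methylglyoxal route to
1,2-propanediol), a proton-explicit electron transport chain, both
transhydrogenases, and a biomass equation.  Conventions:

* Water, cytosolic protons and free phosphate are not balanced; CO2 and
  bicarbonate are one species.  Cofactor pairs (ATP/ADP, NAD(P)/NAD(P)H,
  quinone/quinol) carry no carbon.
* The periplasmic proton pool `hpp` is an explicit, balanced species.  The
  pumping NADH dehydrogenase deposits 4 H+ per NADH, the ATP synthase
  conserves 3 H+ per ATP (reversibly, so surplus ATP can be dissipated), and
  a leak reaction dissipates surplus proton motive force.  All energy
  coupling in the model, including that of the electrode scenarios, flows
  through this pool.
* The membrane transhydrogenase (R47) forms NADPH from NADH at a cost of
  0.33 ATP equivalents per transhydrogenation; the soluble transhydrogenase
  runs the opposite direction for free.
* External species (ids ending `_ext`) are exchangeable and excluded from
  the steady-state matrix.  Every build enables exactly one substrate
  uptake; all other carbon exchanges are secretion-only, so yields are
  always relative to a single carbon source.

### The biomass equation

R1 drains the standard eleven precursors at the textbook *E. coli* demands
(expressed in eighths of a mmol/gDW so that exact arithmetic stays small -
the rounding is well below any effect visible in a yield), consumes NADPH
and ATP and releases NADH and CO2; one biomass unit carries exactly 40
C-mmol (48 % carbon by mass).  The ATP demand, 58.75 mmol/gDW including
growth-associated maintenance, is the one deliberately calibrated parameter
of the network: it is set so that the anaerobic glucose network without
electrode reaches a 26.5 % maximum biomass carbon yield.  All other yields
are predictions, not fits.

### Why the methylglyoxal 1,2-propanediol branch is native

With glycerol as the only carbon source, every catabolic route of the core
network is NADH-neutral or NADH-producing, and biomass formation itself
produces NADH; without a net NADH-consuming branch anaerobic growth on
glycerol is stoichiometrically impossible (the LP is feasible only at zero
growth).  *E. coli* resolves this in vivo through the methylglyoxal route to
1,2-propanediol, which consumes two NADH per triose phosphate.  The branch
is therefore part of the main network (R17) rather than an appended
engineered pathway, and "1,2-PDO" as a screened product simply reads the
native secretion.

### Condensed production pathways

Each non-native product is one or two lumped reactions derived from the
standard engineered route, carbon-balanced exactly, with the cofactor
bookkeeping of that route (see the registry in `R/core_model.R` for the
per-product provenance notes).  Two choices deserve mention:

* The 1,3-propanediol route phosphorylates its sugar with one energy-rich
  phosphate per product: from glucose the PTS consumes one PEP and the
  phosphofructokinase one ATP per two trioses, so the lumped pathway
  reproduces the textbook summary (half a glucose, one ~P, two NADH per
  propanediol).  The "~P from ATP or PEP" ambiguity is resolved mechanistically:
  the PTS itself is PEP-driven, further phosphate comes from ATP.
* para-aminobenzoate costs one ATP more than para-hydroxybenzoate (the
  glutamine amide-donor step); this single difference reproduces the
  distinct printed ceilings of the two aromatics.

## The electrode scenarios

Electrons are an unbounded external pseudo-species exchanged in pairs (one
redox carrier per two electrons); the mediator cycle is collapsed into that
exchange.

| id   | side    | reaction                      | energy coupling            |
|------|---------|-------------------------------|----------------------------|
| Cat1 | cathode | 2 e- + NAD+ -> NADH           | 2 H+/NADH into `hpp` (2/3 ATP) |
| Cat2 | cathode | 2 e- + NAD+ -> NADH           | none                       |
| An1  | anode   | QH2 -> Q + 2 e-               | via the pumping NADH dehydrogenase |
| An2  | anode   | NADH -> NAD+ + 2 e-           | none                       |

An1 drains the quinol pool: electrons from NADH reach the anode through the
proton-pumping NADH dehydrogenase of the core network, which is what makes
An1 ATP-coupled (4 H+ per NADH at the defaults, i.e. 2 per electron); the
`an1_pumping` parameter adds any further pumping at the mediator-oxidising
step and defaults to zero.  This quinol formulation also lets other quinol
donors (succinate, glycerol-3-phosphate, formate, lactate) respire onto the
anode, which is essential for the large anodic biomass gains.  Under Cat1
the charge imbalance of cathodic NAD+ reduction drives one proton per
electron through the ATP synthase.  `calibrate_energetics()` grid-searches
the two free pumping ratios (An1 extra pumping, aerobic oxidase pumping)
against anchor yields over rationals with small denominators; the shipped
defaults (0 and 5/2) come from that calibration against the anodic and
aerobic glucose biomass ceilings.

A subtlety of scenario comparisons: adding an electrode reaction can only
enlarge the flux cone, so an unrestricted maximum under a cathodic scenario
can never be lower than without it.  Statements that a cathodic scenario
*decreases* a maximum therefore refer to maxima over electrode-using modes
only; the package reports unrestricted LP ceilings and leaves
electrode-conditioned statements to the mode census
(`mode_census(modes, net, function(v, n) v[["R_eet"]] > 0)`).

## The analytics

For a mode with flux v, the carbon yield of product p from substrate s is
100 * v_p C_p / (v_s C_s) with C the carbon atom counts (biomass uses its
40 C-mmol unit content).  `max_yield()` maximises this over a mode set
(ties broken toward fewer by-products, then canonical order),
`growth_coupled_max_yield()` restricts to modes with positive biomass,
`by_product_spectrum()` decomposes a mode's secreted carbon (it sums to
100 % by carbon conservation), `scatter_table()` tabulates biomass against
product yield for all modes, and `mode_census()` counts modes satisfying a
predicate.  The degree of reduction, (4a + b - 2c - 3d + 6e + 5f)/a for
C_a H_b O_c N_d S_e P_f, is exposed as `degree_of_reduction()`; it is the
classical electron-availability index that the screen shows to be a poor
predictor of electrode benefit.

`lp_max_yield()` computes the same ceilings independently by linear
programming over the flux cone with substrate uptake fixed to one.  By cone
theory the LP optimum equals the maximum over elementary modes, which makes
the two routes mutual cross-checks; the test suite enforces agreement to
1e-9 on every network small enough to enumerate.

## Numerical choices

* **Exact rational arithmetic end to end.**  Elementarity is a combinatorial
  property; floating-point tolerances corrupt it.  Stoichiometry is parsed
  to exact rationals (`0.33` is 33/100), modes are primitive integer
  vectors, and all rank/nullspace decisions are exact.  Doubles are used as
  exact integers (valid below 2^53) with overflow guards; oversized
  candidate rays are re-derived from the original constraints rather than
  from accumulated arithmetic.
* **Enumeration** is a nullspace-based double description: the kernel basis
  in column-echelon form is the initial ray set (its pivot coordinates are
  already feasible), the remaining nonnegativity constraints are imposed
  cheapest-first, and candidate pairs pass the combinatorial adjacency test
  (no third ray's processed support inside the union).  Reversible
  reactions are split and the futile forward/backward two-cycles removed;
  before any of this, forced-zero reactions are pruned and metabolites
  touched by exactly two reactions are merged away (a mode-preserving
  compression, undone exactly when modes are folded back).  Output order is
  deterministic: support size, support pattern, then flux values.
* **The LP** is a dense two-phase primal simplex with Bland's rule - these
  stoichiometric LPs are small but highly degenerate, and Bland's rule makes
  termination certain and the vertex deterministic.  Steady-state residuals
  of the returned vertex are verified at 1e-9.
* **Yield comparisons** against reported one-decimal percentages use a 0.5
  percentage-point tolerance.
* **Degenerate inputs**: empty networks enumerate to empty sets; a network
  that cannot consume its substrate yields an explicit infeasibility (not an
  exception); modes that do not consume the substrate have undefined (NA)
  yields; an empty mode census has an undefined fraction.

## The synthetic-network generator

`random_network()` draws small sparse stoichiometric networks (small integer
coefficients from ±1..3, one uptake, one secretion, connectivity enforced,
Mersenne-Twister stream local to the call) for which
`brute_force_efms()` computes the exact ground-truth mode set by testing
every support subset for a one-dimensional sign-feasible restricted
nullspace.  The suite checks engine/oracle set equality across seeded
fixtures spanning reversible fractions 0, 0.3 and 0.6.  These fixtures
exercise the combinatorial engine fully, but they are not biologically
realistic: they have no cofactor pairs, no conserved moieties and no
energy metabolism, so passing them validates the mathematics of
enumeration, not the biology of the core network - that is what the
printed-yield anchors are for.

## Problem sizes and limitations

The test and acceptance runs enumerate modes for the toy and random
fixtures and for moderately sized biological cells; the full screening
cells of this transcription grow beyond 10^5 elementary modes (the network
keeps the organism's parallel respiratory and formate-disposal routes,
which multiply mode counts combinatorially), so screening ceilings for such
cells are evaluated by the LP (provably equal to the mode maximum) and
mode-resolved analytics are demonstrated on smaller networks.  Claims that
are statements about individual modes of a full-size cell - for example
that every high-yield mode of a cathodic cell is growth-free - cannot be
decided by LP bounds and stay open where enumeration exceeds the resource
ceiling; the corresponding tests report that honestly rather than skipping.
Mode
*counts* are reported but never asserted: they are hypersensitive to
transcription details of the network.  The analysis is purely
stoichiometric - no thermodynamics, kinetics, regulation or mediator
electrochemistry - so every ceiling is an upper bound that real strains
will undershoot.
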