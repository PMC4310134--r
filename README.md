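# efmscreen

Stoichiometric screening of **electro-fermentation** — microbial production
with an electrode as extra electron donor (cathode) or acceptor (anode) —
by **elementary flux mode (EFM) analysis** of an anaerobic *Escherichia
coli* core network.

Fermentation yields are often capped by redox balance: a product more
reduced than the substrate demands NADH the cell cannot spare, a more
oxidised one leaves NADH it cannot dispose of. An electrode can lift either
cap, but whether a given substrate–product pair actually benefits — and
whether the answer depends on the electron-transfer mechanism being coupled
to ATP conservation — is a purely stoichiometric question. This package
answers it for glucose, glycerol and fumarate against twenty industrially
relevant products (diols, carboxylic acids, amino acids, aromatics,
alcohols, biomass) under four electrode scenarios plus a no-electrode
control.

## What is inside

* **A 57-species, 75-reaction anaerobic *E. coli* core network** (24
  reversible reactions) in a plain-text reaction-table dialect, with exact
  rational stoichiometry, a proton-explicit electron transport chain and a
  calibrated biomass equation; condensed single-step production pathways
  are appended per product (`build_core_model()`).
* **Electrode scenarios** (`eet_scenario()`): cathodic NAD⁺ reduction with
  (`Cat1`) or without (`Cat2`) proton-motive coupling, anodic electron
  drain from the quinol pool through the proton-pumping NADH dehydrogenase
  (`An1`) or directly from NADH (`An2`).
* **An exact EFM engine** (`enumerate_efms()`): nullspace-based double
  description with mode-preserving network compression, all in exact
  rational arithmetic; an exhaustive brute-force oracle
  (`brute_force_efms()`) and a random-network generator
  (`random_network()`) for verification.
* **An LP oracle** (`lp_max_yield()`): two-phase simplex maximum-yield
  ceilings over the flux cone, provably equal to the EFM maximum.
* **Yield analytics**: carbon yields per mode, maximum and growth-coupled
  ceilings, by-product spectra, mode census statistics, biomass-vs-product
  scatter tables, degree of reduction, and the full
  substrate × product × scenario screen (`screen_all()`, `run_screen()`).

The carbon yield of product *p* from substrate *s* in a flux mode *v* is

    Yield [%] = 100 · v_p C_p / (v_s C_s)

with `C` the carbon atom counts; the degree of reduction of
C_a H_b O_c N_d S_e P_f is `DoR = (4a + b − 2c − 3d + 6e + 5f)/a`.

## Worked example: 1,3-propanediol from glucose

```r
library(efmscreen)

for (scen in c("none", "Cat1", "Cat2")) {
  net <- build_core_model("glucose", "1,3-PDO", scen)
  res <- lp_max_yield(net, "pdo_ext", "glc_ext")
  cat(sprintf("%-5s max carbon yield %.1f%%\n", scen, res$yield_percent))
}
```

```
none  max carbon yield 57.1%
Cat1  max carbon yield 92.9%
Cat2  max carbon yield 62.5%
```

Without an electrode, at most 57.1 % of the glucose carbon can end up in
propanediol: the pathway needs two NADH and one energy-rich phosphate per
product, so part of the substrate must be burned for redox and energy. A
cathode that only delivers NADH (`Cat2`) nudges the ceiling to 62.5 % — the
energy limit remains — while a cathode whose electron influx also drives
ATP synthesis (`Cat1`) lifts it to 92.9 %. The same machinery shows the
mirror case: 2,3-butanediol production *exceeds* its fermentative ceiling
only on an anode (66.7 % from glucose under `An1` or `An2`), although the
product is more reduced than the substrate — the pathway, not the degree of
reduction, decides the beneficial electrode.

Mode-level analytics on an enumerable cell:

```r
net   <- build_core_model("glucose", "1,3-PDO", "Cat1")
modes <- enumerate_efms(net, max_rays = 1e5)   # exact elementary modes
scatter_table(modes, net, "pdo_ext", "glc_ext") # biomass vs product yields
mode_census(modes, net, function(v, n) v[["R_eet"]] > 0)
```

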