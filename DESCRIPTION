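Package: efmscreen
Title: Elementary Flux Mode Screening of Electrically Enhanced Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stoichiometric screening of microbial electrosynthesis and
    electro-fermentation by elementary flux mode (EFM) analysis.  Provides an
    exact-rational elementary mode enumeration engine (double description on
    the split irreversible network), a linear-programming oracle for maximum
    carbon yields, an anaerobic Escherichia coli core network with condensed
    production pathways for twenty industrially relevant products, pluggable
    electrode electron-transfer scenarios (cathodic and anodic, with and
    without coupled ATP synthesis), and yield analytics: degree of reduction,
    maximum and growth-coupled carbon yields, by-product spectra, mode census
    statistics and the full substrate x product x scenario screen.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
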