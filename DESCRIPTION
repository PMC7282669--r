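Package: fibrilMC
Title: Lattice Monte Carlo and Thermodynamic Analysis of Amyloid Fibril
    Elongation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained cubic-lattice Metropolis Monte Carlo simulation of
    amyloid fibril elongation with a temperature-dependent hydrophobic effect,
    together with the analysis layer needed to characterise its thermodynamics:
    free-energy, enthalpy and entropy decomposition of the elongation step,
    state diagrams showing heat and cold denaturation, closed-form
    hydrophobic-effect estimates, least-squares fitting of calorimetric
    elongation enthalpies, isodesmic chemical-depolymerisation fits, and a
    buried-hydrophobic-surface meta-analysis relating the fitted hydrophobic
    strength to sequence hydrophobicity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    seqinr,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
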