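Package: vlpthermo
Title: Thermodynamic Equilibrium Modelling of Multi-Layered Virus-Like Particle Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Equilibrium modelling of the hierarchical, template-driven
    self-assembly of multi-layered icosahedral virus-like particles, with
    the triple-layered rotavirus particle (vp2/vp6/vp7) as the packaged
    default. Provides a law-of-mass-action solver for the 60-species
    assembly ladder under protein mass balances, closed-form single-layer
    diagnostics (pseudo-critical concentration, contact and layer
    association constants), estimation of Gibbs free energies of subunit
    association from in vitro assembly and disassembly efficiencies,
    van't Hoff enthalpy/entropy decomposition, design-space efficiency
    landscapes against an irreversible reference model, and a seeded
    synthetic-data module for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: jsonlite, stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
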