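Package: g4dimer
Title: Coarse-Grained Simulation and SAXS/CD Analysis of Telomeric
    G-Quadruplex Dimers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the stacking equilibrium of telomeric G-quadruplex (G4)
    dimers with a patchy hard-cylinder Monte Carlo model and analyses
    small-angle X-ray scattering (SAXS) and circular dichroism (CD) melting
    data for such systems.  Provides canonical NVT* Metropolis sampling of
    two-cylinder dimers with square-well linker and stacking patches,
    Debye-sum synthesis of SAXS intensities from point-decorated
    configurations, Guinier and pair-distance (p(r)) analysis, dimensionless
    Kratky transforms, stacked-fraction and inter-unit-distance fitting of
    experimental profiles, singular-value-decomposition analysis of CD
    melting matrices with a global three-state unfolding fit, and
    synthetic-data generators that emulate the experimental inputs at known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
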