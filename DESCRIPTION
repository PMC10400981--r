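Package: hemewire
Title: Design and Redox Analysis of Heme Maquette Bundles and Molecular Wires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for parametric design and biophysical analysis of de novo
    four-helix heme maquettes. Builds and fits Crick-parameterised coiled-coil
    bundles, splices helices to extend diheme scaffolds into multiheme
    molecular wires, places idealised bis-histidine ligated heme cofactors and
    measures the geometry of heme chains (edge-to-edge distances, chain span,
    keystone hydrogen bonds). Estimates nonadiabatic electron-transfer rates
    between hemes with the empirical distance ruler, predicts midpoint
    potentials and mutational shifts by Metropolis Monte-Carlo titration of
    coupled proton/electron binding sites under a screened-Coulomb (or
    externally supplied) interaction model, and fits potentiometric redox
    titrations (multi-couple Nernst) and tight-binding (Morrison) ligand
    isotherms. Includes seeded synthetic-data generators so every stage of the
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
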