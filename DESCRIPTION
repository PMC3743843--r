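Package: heavytrack
Title: Heavy-Ion Track Structure Simulation and Clustered DNA Damage Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for DNA damage induced by
    heavy-ion (Fe, C) irradiation. Converts absorbed dose to particle fluence
    and per-nucleus traversal statistics; generates stochastic track-structure
    energy-deposition patterns (track core plus delta-electron penumbra)
    calibrated to a nominal LET; scores single- and double-strand breaks on a
    randomly oriented B-form DNA segment target using direct (>10 eV in the
    sugar-phosphate moiety) and indirect (OH-radical, reaction probability
    0.13) mechanisms with opposite-strand pairing within 10 bp; classifies
    damage by radial distance from the ion trajectory and partitions gammaH2AX
    focus point patterns into clusters; and renders synthetic 3D fluorescence
    z-stacks with realistic blur and noise so that the focus detection and
    cluster-quantification stages can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
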