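Package: agphot
Title: Photophysical Rate Constants and Quantum Yields for DNA-Stabilized
    Silver Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rate-constant and quantum-yield engine for fluorescent
    DNA-stabilized silver nanoclusters (AgN-DNA). Computes radiative rates
    with the Strickler-Berg formula, intersystem-crossing rates from a
    golden-rule expression with a Marcus-Levich-Jortner Franck-Condon
    weighted density of states driven by the spin-orbit coupling matrix
    element and the S1-T1 gap, and internal-conversion rates in an X-H
    promoting-mode approximation. Combines the channels into fluorescence
    quantum yields, branching fractions and excited-state lifetimes.
    Includes Gaussian/Lorentzian broadening of TD-DFT stick spectra, a
    structure toolkit (Kabsch subset superposition, bond and contact
    tables for XYZ/PDB geometries), a validated emitter-descriptor file
    format with packaged reference emitters, and deterministic synthetic
    fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
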