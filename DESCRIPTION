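Package: ripfit
Title: Worm-Like-Chain Analysis of Single-Molecule Pulling Experiments on
    Repeat Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing dual-trap optical-tweezers stretch-relax
    cycles on tandem-repeat proteins tethered via DNA handles: extensible
    worm-like-chain (WLC) mechanics for series-composed tethers, detection of
    unfolding/refolding rips and their forces, branch-wise WLC fitting for
    absolute contour lengths and contour-length changes, and classification of
    cycles as fully folding, misfolded or locked-unfolded.  A kinetic
    Monte-Carlo simulator of constant-velocity pulling on a 15-repeat
    HEAT-protein (Bell-model block kinetics, quasi-static force balance)
    generates realistic synthetic data for the three assay conditions
    (no chaperone, stabilising ligand, folding-blocking ligand) so every stage
    of the pipeline is testable end to end.  Companion ensemble-assay tools
    extract melting temperatures from nanoDSF 350/330 nm ratio curves and fit
    one-site binding constants to fluorescence-polarization titrations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
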