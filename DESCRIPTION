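Package: sbmotion
Title: Structure-Based Models and Domain-Motion Analysis for Macromolecular Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds single-basin all-atom structure-based ("Go-like") force
    fields from a reference structure, including Shadow Contact Map native
    contacts, energy-scale normalization, disorder masking and harmonic
    distance restraints; integrates Langevin dynamics in reduced units; and
    analyses domain motion through Kabsch superposition, Euler-Rodrigues
    rotation/tilt decomposition, per-residue average spatial deviation and
    histogram free-energy profiles. Ships a seedable synthetic two-domain toy
    system so the whole pipeline is testable without external structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
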