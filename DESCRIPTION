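Package: epiensemble
Title: Ensemble Epistasis from Conformational Thermodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models epistasis that arises from a protein's thermodynamic
    ensemble: when mutations have different energetic effects on different
    conformations, Boltzmann redistribution of the conformational populations
    makes their combined effect on ensemble-averaged observables nonadditive,
    even when effects are strictly additive within every conformation.
    Provides Boltzmann-weighted free-energy averaging over conformations,
    double-mutant-cycle epistasis with magnitude, sign, and reciprocal-sign
    classification, ligand-linkage titrations of epistasis against effector
    chemical potential, parameter-space regime scans, a vectorised virtual
    deep-mutational-scan engine over per-conformation stability-effect tables,
    and a synthetic generator for such tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
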