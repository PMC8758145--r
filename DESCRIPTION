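Package: sarmact
Title: Dual-Site Effector Kinetics, Binding and Structural Analysis of SARM1 Activation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying allosteric activation of the axon-degeneration
    NADase SARM1 by pyridine mononucleotide effectors such as NMN and the vacor
    metabolite VMN. Implements a dual-site activator/inhibitor extension of the
    Michaelis-Menten rate law with Hill cooperativity and bounded multi-start
    least-squares fitting; extraction of specific activities from discontinuous
    NAD-consumption assay time courses under a substrate-consumption cutoff;
    simulation and one-site fitting of isothermal titration calorimetry
    isotherms with overflow-cell dilution bookkeeping; and Kabsch rigid-body
    superposition of ARM-domain C-alpha coordinates with iterative outlier
    rejection and polar-contact enumeration. A seeded synthetic-data layer
    emulates the statistical structure of each experiment so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    generics,
    minpack.lm,
    lhs,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    knitr,
    rmarkdown
Config/testthat/edition: 3
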