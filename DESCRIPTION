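Package: regiqa
Title: Relative Energy Gradient Analysis of IQA Energy Partitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing Interacting Quantum Atoms (IQA) and
    Interacting Quantum Fragments (IQF) energy partitions along a
    conformational control coordinate with the Relative Energy Gradient
    (REG) method. Reads and validates per-geometry energy-term tables in a
    documented CSV interchange schema, checks the additivity of the energy
    partition, splits classical electrostatics into charge-transfer and
    polarisation contributions, aggregates atomic terms into fragment
    interactions, computes REG slopes with correlation diagnostics and
    rankings, forms REG Ratios for cross-system comparison, and compares
    computed conformer energy differences against experiment. A seeded
    synthetic-profile generator with known ground truth makes every
    pipeline stage testable without wavefunction data.
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
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
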