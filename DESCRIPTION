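Package: chromarch
Title: Comparative Hi-C Chromatin Architecture Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for comparative analysis of binned
    Hi-C contact maps between two biological conditions. Implements matrix
    balancing (iterative correction), distance-decay expected profiles and
    observed/expected transforms, A/B compartment calling from the first
    principal component of the O/E correlation matrix, TAD-like domain
    detection by insulation score (with an arrowhead-transform caller as a
    cross-check), focal loop detection with a donut local background and
    aggregate peak analysis, differential contact detection by joint loess
    normalization on the MD plot with per-distance robust Z-scores and BH
    correction, and hypergeometric enrichment of differentially expressed
    genes and differential contacts in common versus changed architecture
    regions. A ground-truth synthetic contact-map generator emulating
    two-condition experiments (distance decay, compartment checkerboard,
    domain blocks, focal loops, programmed alterations, Poisson noise) is
    included for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
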