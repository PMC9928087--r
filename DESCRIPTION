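Package: rsmregulon
Title: Plasmid-Borne Rsm/CsrA Regulators: Carriage Surveys, Binding-Site
    Prediction, and Post-Transcriptional Regulon Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying plasmid-encoded homologues of the Rsm/CsrA
    family of bacterial translational regulators. Provides comparative
    statistics of regulator carriage across plasmid collections (contingency
    tables, Fisher exact, Kolmogorov-Smirnov and size-distribution
    comparisons), a sequence-plus-structure binding model (AnGGA/GGA motif
    scanning in gene 5' windows, maximum base-pairing folding of short
    probes, hairpin-apex exposure classification, regulon prediction),
    quantitative surface plasmon resonance analysis (theoretical Rmax,
    percent Rmax, binding calls, two-factor comparisons), Jukes-Cantor
    divergence comparisons of chromosomal versus plasmid homologues,
    integration of mRNA and protein fold-change tables into a
    post-transcriptional regulon classification, and bacterial trait
    statistics (relative fitness, end-point conjugation rate, Miller units,
    swarming index). Synthetic-data generators emulate every input so the
    full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
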