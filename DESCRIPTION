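Package: tomahaqr
Title: Targeted Quantification of Intramembrane Protease Products by
    Triggered Multiplexed Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing triggered, multiplexed,
    absolute-quantification (TOMAHAQ-style) targeted proteomics experiments
    that monitor protease cleavage of membrane substrates in purified
    organelles. Provides in-silico proteolysis and half-tryptic peptide
    design for cleavage-site monitoring (e.g. BACE1 and gamma-secretase
    processing of APP), label-aware mass and fragment-ion computation, a
    synthetic LC-MS run generator with per-scan ground truth, an offline
    re-implementation of the triggered acquisition decision cascade
    (real-time peak matching, SPS ion selection, prescan-scaled injection
    times), reporter-ion quantification with isotopic impurity correction
    and knockout-channel background, SIM-based absolute quantification
    against spiked trigger peptides, and organelle-enrichment statistics
    with two-stage Benjamini-Hochberg adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    jsonlite
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
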