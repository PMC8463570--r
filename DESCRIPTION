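Package: cophylorestrict
Title: Host-Restricted Clade Detection and Co-Phylogenetic Test Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects host-restricted, mixed-host and unique-to-captive clades of
    amplicon sequence variants (ASVs) on a symbiont phylogeny, calibrates clade
    sizes against a fixed-margins (curveball) permutation null, quantifies
    presence/absence strain sharing among hosts with the Sorenson index and
    permutation t-tests, and stress-tests three distance-based co-diversification
    statistics (Hommola correlation test, ParaFitGlobal, PACo Procrustes m2)
    against randomized host phylogenies. Ships a synthetic-data generator that
    emulates wild/captive great-ape incidence data under co-diversification,
    host-switch, environmental-filtering and captive-mixing regimes so the whole
    pipeline is testable without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    S4Vectors,
    IRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    vegan,
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
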