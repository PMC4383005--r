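Package: NotchCourse
Title: Staged Neural Differentiation Time-Course Analysis of Notch-Active
    and Notch-Inactive Progenitor Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of staged human embryonic stem cell to neural
    progenitor expression time courses in which each post-ES stage is
    split by FACS into Notch-active (HES5+) and Notch-inactive (HES5-)
    populations. Provides probe-to-gene collapse, a range/level variation
    filter, baseline (hESC) subtraction, temporal-pattern classification
    of k-means cluster centroids against a grammar of up/flat/down codes,
    stage-specific Notch-active gene selection by dual fold-change
    thresholds, marker-panel heatmap normalizations, the 2^-dCT qPCR
    relative-abundance pipeline, and a synthetic-data generator with
    planted ground truth so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
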