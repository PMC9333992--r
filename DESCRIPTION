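Package: cohortwiring
Title: Temporal-Cohort Connectivity Analysis for Larval Nerve Cord Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for testing whether neurons born in the same
    temporal cohort of a neuroblast lineage share synaptic input partners.
    Provides input accounting on synaptic edge tables (source-type
    composition, sensory breakdowns, synapse-count histograms with
    Kolmogorov-Smirnov comparison, left-right pairing and highly-connected
    filters, class composition), a permutation-null Euclidean-distance
    similarity statistic on per-neuron input vectors with z-score
    significance calls, birth-order proxies from skeleton morphology
    (cortex neurite length and its correlation with birth rank), and a
    seeded synthetic-connectome generator with sharp, graded, and null
    wiring models so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    igraph,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
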