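Package: baseEditScreen
Title: Design and Analysis of Pooled Base-Editing Fitness Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-scale cytidine base-editor (Target-AID style)
    screens in which guide RNAs double as barcodes for the fitness effect of
    the mutations they induce. Covers design of guide libraries against coding
    sequences (editing-window cytosine filters, co-editing risk categories,
    uniqueness and restriction-site checks), prediction of per-guide
    mutational outcomes with protein consequences and stop-codon-generating
    guide classification, read-to-guide matching with synthesis-error
    detection, abundance-change statistics against a synthesis-error null
    distribution with FDR-controlled calling of guides with negative fitness
    effects, enrichment analyses of substitution patterns and annotations,
    and a synthetic-screen generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
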