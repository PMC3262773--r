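Package: mircoord
Title: Regulatory Coordination of Genomically Clustered microRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analyses the regulatory coordination of genomically clustered
    microRNAs on a directed miRNA-transcription factor regulatory network.
    Calls miRNA clusters from precursor coordinates by distance chaining,
    classifies them as homo- or hetero-clusters via normalized family
    entropy, detects dense network modules with an MCODE-style algorithm,
    computes pairwise target-overlap statistics over bounded k-step
    regulation paths, and assesses enrichment, module cluster entropy and
    target-overlap contrasts with permutation null models. Ships a
    synthetic scenario generator with planted ground truth for every
    analysis stage, plus an end-to-end pipeline with a file-based
    configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
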