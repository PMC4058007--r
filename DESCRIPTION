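Package: arachnotox
Title: Venom-Gland Transcriptome Mining for Spider Toxin Discovery
Version: 0.1.0
Authors@R:
    person("Maintainer", "Arachnotox", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for discovering venom-gland-specific
    transcripts and candidate toxins from a multi-tissue spider
    transcriptome: six-frame ORF prediction with best-protein selection,
    redundancy collapse of identical-over-overlap proteins, eCPM/FPKM
    expression normalisation with exclusive and upper-quantile ratio
    classification of venom-gland-specific transcripts, keyword-based toxin
    category tagging, cysteine-rich small-protein and inhibitor-cystine-knot
    framework screens, single-linkage protein family clustering across an
    identity/coverage grid, length-bias-corrected GO overrepresentation by
    weighted resampling, and integration of venom mass-spectrometry peptide
    identifications into a proteome-confirmed secretome. Includes a seeded
    synthetic-data generator with planted venom gene families so every stage
    is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
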