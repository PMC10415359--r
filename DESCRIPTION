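Package: g4origin
Title: Clustered G-Quadruplex Motifs and Replication Origin Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to link clustered (dimeric to hexameric) potential
    G-quadruplex motifs (pG4s) to DNA replication origins. Detects pG4s on
    both genome strands, classifies them into monomeric, clustered and
    oversize runs, builds GC- and size-matched random genomic backgrounds,
    quantifies feature enrichment by logistic-regression log-odds ratios
    with Wald tests (including the strand-aware origin/pG4 variant),
    computes anchored sliding-window coverage profiles, scores and
    stratifies origin strength from short-nascent-strand reads, and
    processes Repli-seq S-phase fraction counts into weighted-average
    replication-timing profiles and replication-timing shift statistics.
    Includes a synthetic-data generator with full ground truth (planted
    motifs, origins with configurable log-odds association, nucleosome-free
    regions, H2A.Z marks, SNS reads, and S-phase fraction counts with a
    planted local timing advance) so every stage can be validated against
    known parameters, plus a pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    lmtest,
    optparse,
    sandwich,
    stringr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
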