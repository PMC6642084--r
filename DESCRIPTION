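Package: cladescan
Title: Clade-Level Gain and Loss Detection from Gene Presence/Absence Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Phylotranscriptomic analysis of gene family gain and loss across
    clades of a phylogeny. Converts profile-HMM hit tables from de novo
    transcriptome searches into binary presence/absence calls (bitscore
    thresholding and dual-HMM score-ratio annotation), detects statistically
    skewed distributions of gene families across named clades and along a
    tree with an exact two-sided 2xK Fisher test computed by log-space table
    enumeration, tests co-gain and co-loss of enzyme pairs, collapses
    uninformative tree nodes into terminal clusters, validates a sequence
    marker against lipidomic DGTS/PC abundance ratios, and simulates binary
    trait evolution with transcriptome detection dropout for power and
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
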