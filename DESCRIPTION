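Package: velvetsurvey
Title: Survey of Velvet-Domain Protein Families Across Simulated Fungal Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for kingdom-wide protein-family domain
    surveys, modeled on the velvet family of fungal transcription regulators.
    Provides a synthetic proteome generator that plants multi-clade domain
    families with known ground truth; a position-specific log-odds profile
    scanner with affine-gap local alignment and a domain-completeness filter;
    per-genome and per-group survey statistics including the N/middle/C
    domain-position classifier; neighbor-joining phylogenies with bootstrap
    support and reference-anchored clade naming; per-clade consensus logos,
    information content, cross-clade conserved-site calling and characteristic
    motif segmentation; and box-plot/t-test reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    jsonlite,
    phangorn,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
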