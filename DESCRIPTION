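Package: svpath
Title: Germline Structural Variant Pathogenicity Discovery
Version: 0.1.0
Authors@R: person("svpath developers", role = c("aut", "cre"),
    email = "svpath@example.org")
Description: An end-to-end workflow for discovering rare, potentially
    pathogenic germline structural variants (SVs) in case cohorts.
    Integrates per-sample callsets from two SV callers under a breakpoint
    concordance rule, applies population-level genotype quality control
    and ancestry-stratified allele frequency estimation, classifies SVs
    against canonical transcript models into gene-impact categories,
    matches SVs to a clinical catalog, and runs a consensus pathogenicity
    cascade combining per-tool score thresholds, cancer gene-set support,
    rarity gates and curated gene roles. Ships a deterministic synthetic
    cohort generator with a planted-truth table so every stage is testable
    without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
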