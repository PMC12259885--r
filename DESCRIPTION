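Package: defensome
Title: Census and Comparative Analysis of Anti-Phage Defense Systems in
    Annotated Prokaryotic Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the downstream analysis of anti-phage defense system
    annotations in cohorts of prokaryotic genomes (isolates or
    metagenome-assembled genomes). Reads gene, defense-system
    (DefenseFinder-style), mobile-genetic-element (MGE) and genome-quality
    tables; computes per-genome defensome profiles, family prevalence and the
    first-line/accessory partition; detects defense islands by gene-order
    chaining; quantifies defense-system/MGE and defense-system/island
    colocalization with observed/expected ratios and chi-square tests; fits a
    logistic upper-envelope model for the trade-off between defense-system
    counts and adaptive traits (antibiotic-resistance, metal-resistance and
    virulence genes); matches CRISPR spacers to phage protospacers under
    mismatch and coverage thresholds and tabulates phage anti-defense genes.
    A seeded synthetic-cohort generator with planted ground truth supports
    validation of every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
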