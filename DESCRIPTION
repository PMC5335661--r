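Package: sigreverse
Title: Signature-Based Drug Repurposing by Connectivity Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in silico drug-repurposing pipeline for anti-fibrotic
    discovery built around transcriptome signature reversal. Constructs a
    directional differential-expression signature from a two-group
    expression matrix by permutation t-tests with Benjamini-Hochberg FDR
    control and ortholog mapping; scores the signature against a
    compound-perturbation rank database with Kolmogorov-Smirnov tag
    enrichment (connectivity) statistics and permutation p-values; selects
    signature-reversing compounds; quantifies target-gene overlap between
    gene sets with exact hypergeometric probabilities against a
    protein-coding background; and validates candidate markers by
    mean-plus-one-standard-deviation stratified Kaplan-Meier and log-rank
    survival analysis. A synthetic-data module generates inputs with
    planted ground truth (differential expression, signature-reversing
    compounds, group-dependent hazards) so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
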