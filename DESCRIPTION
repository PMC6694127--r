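Package: metasig
Title: Integrated Multi-Cohort Transcriptomic Signature Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrated analysis of case/control transcriptomic
    signatures across multiple cohorts and tissues: per-dataset differential
    expression by fold change and Wilcoxon rank-sum test, cross-dataset
    similarity via Spearman correlation of fold-change vectors with classical
    multidimensional scaling and a tissue-clustering permutation test,
    direction-of-change concordance matrices, separate over-representation
    analysis of up- and down-regulated gene lists, connectivity-map style
    KS enrichment scoring of ranked drug profiles for signature-reversal
    prediction, drug-set enrichment, and permutation nulls for cross-group
    overlap statistics. Includes a synthetic-data generator with planted,
    known structure so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
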