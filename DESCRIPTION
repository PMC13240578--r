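Package: clonoshare
Title: Cross-Compartment Clonal Sharing Analysis for Paired Single-Cell
    Expression and Immune-Repertoire Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking expanded T- and B-cell clonotypes across
    anatomical compartments (lung tissue, bronchoalveolar lavage fluid, and
    peripheral blood) in paired single-cell expression and receptor-contig
    data. Reads 10x Genomics contig tables, AIRR rearrangement tables, and
    Matrix Market count matrices; collapses receptor chains into
    subject-scoped clonotypes; classifies expanded clones into
    compartment-sharing patterns; quantifies clonal expansion, migration and
    state transition with entropy-based repertoire indices; annotates
    unlabelled cells against pattern-level reference transcriptomes by
    Spearman correlation with iterative fine-tuning; and simulates complete
    cohorts with known clonal structure so every stage can be validated
    against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
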