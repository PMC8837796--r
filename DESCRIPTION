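Package: homeodosage
Title: Population-Scale Analysis of Homoeologous Gene Expression Dosage in
    Allopolyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the regulation of homoeologous gene expression
    dosage in allopolyploid populations such as hexaploid wheat. Provides
    genome-partitioned variance-component (multi-GRM REML) analysis of
    expression, cis/trans eQTL mapping with LD-based interval merging and
    permutation-calibrated false discovery rates, homoeolog expression-bias
    and dosage-compensation statistics, summary-based Mendelian randomization
    with the HEIDI heterogeneity test, eQTL-derived regulatory-network
    construction, and expression-burden and ridge-regression trait
    association. Includes a synthetic allohexaploid cohort generator with a
    known regulatory architecture so every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    igraph,
    jsonlite,
    limma,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
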