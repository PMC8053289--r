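Package: hetexpr
Title: Heterosis and Gene Expression Inheritance in Reciprocal Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of mid-parent heterosis and gene expression
    inheritance in a four-group reciprocal-cross design (two parental
    lines and their two F1 crosses). Implements mid-parent heterosis
    percentages with a one-sample t significance test, negative-binomial
    Wald differential expression with median-of-ratios normalization and
    Benjamini-Hochberg adjustment, classification of differentially
    expressed genes into twelve expression-pattern classes grouped as
    additive, dominant or overdominant inheritance, hypergeometric
    gene-set over-representation analysis, and a synthetic-data generator
    that plants known inheritance patterns so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
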