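Package: crossmas
Title: Dosage-Sensitive Differential Expression with Magnitude-Altitude
    Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Differential expression analysis for three-condition dosage
    experiments (reference, knockdown, overexpression of a driver gene)
    from raw RNA-seq counts: trimmed-mean-of-M-values (TMM)
    normalization, negative-binomial generalized linear models with
    quasi-likelihood F-tests, Magnitude-Altitude scoring (MAS) of genes
    by effect size and significance, Cross-MAS partitioning of
    differentially expressed genes into condition-unique and shared sets,
    correlation- and directionality-based selection of a dosage-sensitive
    biomarker panel, and evaluation of panel discriminability by
    principal component analysis and multinomial logistic regression.
    Includes a negative-binomial count simulator with planted,
    truth-labelled dosage-sensitive gene classes for end-to-end
    validation, and a local hypergeometric over-representation test for
    user-supplied gene sets.
License: MIT + file LICENSE
Imports:
    jsonlite,
    limma,
    nnet,
    stats,
    utils,
    withr,
    yaml
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
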