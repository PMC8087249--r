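Package: grexml
Title: Multi-Algorithm Genetically Regulated Expression Prediction and TWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains per-gene cis-window gene expression prediction models with
    elastic net, random forest, support vector regression and K nearest
    neighbor under nested and grid-search cross-validation, evaluates their
    portability across populations of diverging ancestry, and runs
    transcriptome-wide association tests of predicted expression against a
    quantitative phenotype. Includes genotype quality control (call rate,
    Hardy-Weinberg exact test, minor allele frequency, strand-ambiguity,
    linkage disequilibrium pruning, relatedness screening, genotype principal
    components), expression preparation (probe collapse, abundance filtering,
    quantile and rank-inverse-normal normalization, hidden-factor
    residualization), and a Balding-Nichols multi-population cohort simulator
    with known cis-eQTL architectures so the full pipeline is testable
    without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    glmnet,
    jsonlite,
    limma,
    ranger,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
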