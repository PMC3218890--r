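Package: cisreg
Title: Cis-Regulatory Model Selection for Expression QTL Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling cis-regulation of gene expression from
    dense local variant panels and multi-probe expression data. Implements
    per-probe standardization, probe-correlation analysis with
    representative-signal compositing, linkage-disequilibrium pruning of
    additive genotype dosages, forward-entry multiple linear regression
    with likelihood-ratio comparison of nested models and the Davidson
    and MacKinnon J-test for non-nested models, EM haplotype phasing
    under Hardy-Weinberg equilibrium, and haplotype-dosage association
    with expression. A synthetic-data module generates
    haplotype-structured genotypes and expression with known ground
    truth so that every analysis stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
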