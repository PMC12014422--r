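Package: cismvmr
Title: Multivariable Mendelian Randomization with cis-eQTL Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locus-by-locus multivariable Mendelian randomization (MVMR) using
    gene-expression quantitative trait locus (cis-eQTL) and disease GWAS
    summary statistics. Implements matrix completion for the block-missing
    cis-eQTL effect matrix, instrument selection robust to correlated
    horizontal pleiotropy, bias-corrected causal estimation (MRBEE) with
    inference that remains valid when linkage disequilibrium is estimated
    from a finite reference panel, SCAD-penalized gene screening, sparse
    gene co-regulation network estimation, and a simulation engine for the
    validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
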