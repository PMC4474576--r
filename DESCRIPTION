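Package: epitree
Title: Conditional Gene-Expression Modelling from Promoter Chromatin State
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predictive modelling of mRNA transcript abundance from
    promoter-localised histone-modification ChIP-seq signal and RRBS DNA
    methylation. Quantifies gene-level chromatin scores (shifted sum-of-tags
    histone scores and four promoter methylation scores), fits arsinh-linear
    regression models of RPKM-normalised expression scored by adjusted R
    squared, derives putative regulatory roles from PCA loadings, and
    discovers latent regulatory classes (methylated and bivalent promoters)
    with a binary decision tree of regression models whose categorisation
    thresholds are selected by an unsupervised scan against a
    random-gene-set null. Includes a matched synthetic-data generator with
    planted regulatory classes and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
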