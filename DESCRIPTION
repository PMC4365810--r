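Package: sgse
Title: Spectral Gene Set Enrichment for Unsupervised Genomic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised, competitive testing of the association between gene
    sets and the principal-component structure of a genomic data matrix.
    Per-PC gene set p-values are computed with a correlation-adjusted
    competitive test on Fisher-transformed gene-PC correlations and combined
    across principal components with the weighted Z-method, using weights
    equal to each PC variance optionally scaled by the lower-tail
    Tracy-Widom probability of its eigenvalue. Includes the benchmark
    cluster-based enrichment test (k-means plus Pearson chi-squared on
    cluster membership) and a simulation harness for type-I-error and power
    studies under identity, single-factor and two-factor spiked covariance
    models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    cluster,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
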