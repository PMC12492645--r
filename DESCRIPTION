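Package: gxeldr
Title: Genome-Level Gene-Environment Interaction Analysis from Summary
    Statistics via LD Eigenvalue Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimates the genome-level gene-environment (GxE) interaction
    proportion and the GxE genetic covariance from GWAS and genome-wide
    interaction scan (GWIS) summary statistics, exploiting the full
    linkage-disequilibrium (LD) structure of the genome through
    eigen-decomposed block LD matrices.  Provides moment-condition
    estimators on whitened Z-score products with iteratively reweighted
    least squares, delete-block jackknife inference, a joint Mahalanobis
    test of the interaction proportion and the GxE genetic covariance, a
    correction for confounding induced by heritable environmental
    variables, a diagonal-LD-score baseline estimator, and a block-LD
    simulation engine for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
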