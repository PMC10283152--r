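Package: novatest
Title: Detecting Genes with Location-Dependent Noise Variance in Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models each gene's spatial expression profile with a homoscedastic
    Gaussian process and with an approximate heteroscedastic Gaussian process
    (a second GP fitted to squared-residual variance estimates), compares the
    two models by negative log predictive density over repeated random
    train/validation splits, and calls genes whose heteroscedastic fit is
    significantly better ("noisy genes") using an exact Wilcoxon signed-rank
    test with Benjamini-Hochberg FDR control. Includes quality-control
    filtering and Anscombe variance stabilisation for spot-by-gene UMI count
    matrices, Otsu/Jaccard clustering of the detected spatial noise-variance
    patterns, marker-set enrichment scoring against expression-binned control
    sets, bivariate Spearman association of noise maps with explanatory
    variables, and a synthetic-data generator for calibration studies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
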