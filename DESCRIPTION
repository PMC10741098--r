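Package: polyratio
Title: ORF-Length-Adjusted Light-to-Heavy Polysome Ratio Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of miRNA-mediated retention of target mRNAs in
    translationally less-active light polysomes from comparative
    polysome-profiling RNA-seq of wild-type and miRNA-deficient (DICER1
    knockout) cells. Computes light-to-heavy polysome mRNA abundance
    log-ratios from HTSeq-count tables, adjusts them for ORF length using
    the residuals of a from-scratch local (LOESS) regression, double-adjusts
    wild-type against mutant ratios to cancel miRNA-independent regulation,
    and provides binding-site-count trend summaries, group and dispersion
    tests, resampling null distributions, and rank-based gene-set enrichment.
    Includes a negative-binomial simulator of polysome count data with
    planted, recoverable effects for validation and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
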