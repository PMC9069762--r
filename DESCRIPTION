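Package: pleioscan
Title: Cross-Trait Pleiotropy and Causal Inference from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying shared genetic architecture between two
    complex traits from genome-wide association summary statistics alone:
    harmonization of per-SNP effect estimates across studies, intergenic-SNP
    genomic control, greedy linkage-disequilibrium pruning, conditional
    quantile-quantile and fold-enrichment stratification, conditional and
    conjunctional false discovery rate locus discovery, a method-of-moments
    genetic covariance and correlation estimator with block-jackknife
    uncertainty, and a two-sample Mendelian randomization suite
    (inverse-variance weighted, Egger regression, Cochran's Q, leave-one-out,
    instrument F statistics, PRESSO-style outlier detection, and power).
    Includes a paired-GWAS simulator with block-structured linkage
    disequilibrium and a four-component bivariate causal-effect mixture, so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    data.table,
    jsonlite,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
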