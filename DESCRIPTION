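Package: methylBB
Title: Beta-Binomial Regression for Differential Methylation in
    Multifactor Bisulfite Sequencing Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects differentially methylated cytosines and regions from
    whole-genome bisulfite sequencing (WGBS) count data in general factorial
    designs. Each site is modelled with a beta-binomial regression (logit
    link, common per-site dispersion) fitted by maximum likelihood; the test
    factor is assessed with a full-versus-reduced log-likelihood ratio test.
    Per-site p-values are combined across neighbouring sites with the
    weighted Z (Stouffer-Liptak) method using distance-binned autocorrelation
    estimates, corrected by the Benjamini-Hochberg procedure, and merged into
    differentially methylated regions with log-odds-ratio and minimum
    methylation-difference summaries. A simulator reproduces benchmark
    datasets with beta-distributed methylation levels and scores calls with
    the Jaccard index.
License: GPL (>= 3)
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
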