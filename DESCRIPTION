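Package: radgs
Title: Genomic Selection Evaluation with In Silico 2b-RAD Marker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating reduced-representation (2b-RAD) genotyping
    in genomic selection. Simulates diploid genomes with injected SNPs,
    locates type IIB (BsaXI) restriction tags and reduced-tag-representation
    (RTR) subsets in silico, builds high/medium/low density marker panels,
    runs forward-in-time Fisher-Wright burn-in and family-based mating
    designs with heritability-controlled phenotypes, and fits seven genomic
    prediction models implemented from first principles (pedigree BLUP,
    G-BLUP, RR-BLUP, BayesA, BayesB, Bayesian LASSO, and LASSO), together
    with cross-validated and over-generation accuracy evaluation, REML
    heritability estimation, marker quality control, and principal component
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    knitr,
    rmarkdown
Config/testthat/edition: 3
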