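Package: admixkin
Title: Kinship, Population Structure, and Mixed-Model Association in Admixed Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for relatedness inference in admixed
    multi-generation pedigrees. Provides a gene-dropping simulator with known local
    ancestry (Balding-Nichols differentiated allele frequencies, Dirichlet admixture,
    Haldane recombination), marker-selection designs (agnostic stride, common-variant
    selective, frequency-homogenizing), four kinship estimators (pedigree recursion,
    KING-robust, method-of-moments IBD, EM maximum-likelihood IBD) plus the
    PC-adjusted moment estimator with individual-specific allele frequencies,
    ratio-of-sums and per-marker-standardized genetic relationship matrices with PCA
    and ancestry-capture regression, an EMMAX-style mixed-model association scan with
    admixture mapping on local-ancestry dosages and genomic control, and longitudinal
    variance-curve estimation of age-varying heritability with cubic splines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    splines,
    withr,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
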