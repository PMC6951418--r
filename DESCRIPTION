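Package: elincnet
Title: Classify Intergenic lncRNAs into Enhancer-Associated and Canonical
    Classes from Chromatin Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies enhancer-associated intergenic long non-coding RNAs
    (elincRNAs) and distinguishes them from canonical, promoter-like lincRNAs
    using multi-omic interval features. High-confidence training labels are
    derived from a permutation test on H3K4me1/H3K4me3 read-count ratios in
    TSS windows; features (histone-mark coverage ratios, DNA-methylation beta
    means, CpG-island/repeat/TF coverage) are extracted over TSS and gene-body
    regions; an elastic-net family regularized regression classifier is fit by
    cyclical coordinate descent with cross-validated selection of the mixing
    and penalty parameters. Includes ROC/PR evaluation, overlap-based
    independent test labeling, chromatin-state randomization validation, a
    synthetic-data generator for end-to-end testing, and the published fitted
    seven-feature model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
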