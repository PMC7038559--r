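Package: epiCofactor
Title: Non-Classical Functions of Histone Modification Regulators from
    ChIP-seq Cobinding
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts whether a histone modification regulator (HMR) acts
    at a subset of its genomic binding sites independently of its classical
    histone-mark substrate or product, and ranks candidate cofactors that
    co-bind specifically at those substrate-depleted sites. Builds a binary
    (or quantitative) cobinding design matrix from factor ChIP-seq peak
    sets over the HMR's peaks, regresses the windowed histone-mark signal
    on it with an elastic-net penalty, refits surviving negatively
    associated factors by univariate least squares with a Wherry-adjusted
    R-squared and a permutation test, and partitions the HMR peaks into
    classical and non-classical sites with Otsu's threshold. Ships a
    simulation harness with planted cofactor groups and three
    experimental-variation noise models for specificity and robustness
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
biocViews: ChIPSeq, Epigenetics, Regression, FeatureExtraction,
    GeneRegulation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cofactor-inference.R'
    'genomic-io.R'
    'design-matrix.R'
    'epiCofactor-package.R'
    'site-classifier.R'
    'pipeline.R'
    'simulation.R'
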