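Package: cistransnet
Title: Cis/Trans Gene Co-Expression Network Analysis with Mutual Information
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers gene co-expression networks from RNA-seq count matrices
    with a deterministic equal-frequency-binning mutual information estimator,
    classifies every network edge by genomic relation (same chromosome,
    chromosome arm, cytoband, genomic distance), and quantifies the balance of
    intra-chromosome (cis-) versus inter-chromosome (trans-) co-expression
    across top-k edge cutoffs, between phenotypes, and under sample
    subsampling. Includes count preprocessing (CPM filtering, covariate
    full-quantile correction, trimmed-mean-of-M scaling), permutation
    calibration of MI significance thresholds, moderated-t differential
    expression with expression-trend edge classification, network
    intersection and component statistics, and a synthetic count generator
    that plants cis-block and trans-module covariance structure for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    xml2,
    jsonlite,
    optparse
Config/testthat/edition: 3
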