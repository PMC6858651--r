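Package: SpliceTypes
Title: Prognostic Alternative-Splicing Subtypes from PSI Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying tumour cohorts by prognostic alternative
    splicing. Implements genome-wide survival screening of percent-spliced-in
    (PSI) values (mean-split dichotomization and log-rank testing),
    Monte-Carlo consensus clustering with PAC/RCSI-based selection of the
    number of splicing subtypes, subtype-specific splicing-signature calling
    under a fold-change plus FDR rule, two-group (e.g. IDH-status) related
    event calling, splicing-factor to splicing-event correlation networks,
    and clinical characterization of the resulting subtypes. A synthetic
    cohort generator with planted subtypes, prognostic events and
    factor-event regulation provides ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    igraph,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    cluster,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: AlternativeSplicing, Survival, Clustering, GeneExpression,
    Classification
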