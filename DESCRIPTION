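Package: panConserve
Title: Conserved Co-Expression Modules and Cross-Cancer Prognostic Risk Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds weighted gene co-expression networks per tumor cohort,
    quantifies module preservation across cohorts with permutation Zsummary and
    medianRank statistics, extracts gene sets conserved across groups of
    cancers, stratifies tumor samples by classifier expression, identifies
    survival-associated risk genes, assembles a cross-cancer prognostic gene
    panel, and revalidates it by random resampling. Includes a synthetic
    multi-cancer expression and survival simulator with full ground truth so
    every stage of the pipeline can be exercised and benchmarked without
    access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    survival,
    mclust,
    knitr
biocViews: GeneExpression, Network, Survival, Clustering, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
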