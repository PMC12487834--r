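Package: chemomodules
Title: Radiation-Induced Chemokine Module Discovery and Senescence Assay
    Quantification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Correlation-based discovery of chemokine and chemokine-receptor
    co-expression modules in annotated single-cell expression data, with a
    permutation test for redundant receptor-ligand module interactions,
    leave-one-out module stability, per-patient module scoring against immune
    infiltration, and the supporting quantitative assays of radiation biology:
    linear-quadratic clonogenic survival fits with relative biological
    effectiveness at 10% survival, senescence-associated secretory phenotype
    (SASP) factor scores, flow-cytometric migration indices, and a
    semiautomated SA-beta-galactosidase image quantifier (rolling-ball
    background subtraction, prominence-based maxima segmentation). A synthetic
    data module generates expression matrices with planted correlated modules,
    survival curves, cytokine panels and stained-cell images with known ground
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    EBImage,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
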