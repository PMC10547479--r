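Package: mamscope
Title: Cross-Tissue Identification of Matrisome-Associated Macrophage
    Polarisation States from Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for identifying a matrisome-associated
    macrophage (MAM) polarisation state across tissues from single-cell
    RNA-seq count data. Provides quality control and normalisation,
    silhouette-guided clustering resolution selection with pseudo-bulk
    cluster merging, cross-tissue differential signature derivation,
    elbow-based marker selection, diffusion-map differentiation-propensity
    scoring, regulon activity scoring with diagnostic-odds-ratio and
    specificity prioritisation, and pseudo-bulk ageing association.  A
    synthetic multi-tissue data generator with known ground truth makes
    every stage testable without access to the original cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    igraph,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
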