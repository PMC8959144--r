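Package: ponsquant
Title: Quantitative Neuroanatomy of Corticopontine and Corticospinal
    Projections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying fluorescently labelled neurons and axon
    tracts on atlas-registered serial brain sections. Implements
    atlas-masked counting of labelled somata per cortical area
    (background subtraction, intensity thresholding, circularity
    filtering, colour-coded ROI assignment), corticospinal-tract width
    profiling with area-under-curve summaries and a fasciculation index,
    semi-quantitative 3D point-cloud recording with z-jitter, digital
    slab slicing and group-shift metrics for corticopontine topography,
    histogram-matching intensity normalization, and the associated group
    statistics (one- and two-way ANOVA with Bonferroni-corrected
    contrasts). A synthetic-data module generates section images, tract
    images and point clouds with planted ground truth so that every
    stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    MASS,
    car,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
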