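Package: myoquant
Title: Quantification of Myoblast Fusion, Cell Shape and Engraftment from
    Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of myogenic differentiation
    assays imaged by multi-channel fluorescence microscopy. Provides a
    synthetic-scene simulator with full ground truth (elliptical myoblasts,
    multinucleated myotubes, marker channels, background gradients and
    speckle artifacts); a segmentation pipeline that band-pass
    pre-processes images, detects nuclei by Otsu thresholding and
    watershed, segregates overlapping cytoplasm by nucleus-anchored
    geodesic Voronoi labelling, and scores per-cell moments-based
    eccentricity; assay metrics (fusion index, myotube size classes,
    marker fractions, engraftment summaries); and a statistical layer
    implemented from first principles: factorial and dose-gradient
    logistic models fitted by iteratively reweighted least squares,
    quasi-Poisson count models with Pearson dispersion, random-intercept
    logistic mixed models fitted by adaptive Gauss-Hermite quadrature, and
    linear models, with odds-ratio effect reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
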