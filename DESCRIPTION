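Package: stpspline
Title: Bayesian Spatiotemporal P-Spline Smoothing for Groundwater Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic smoothing of irregular spatiotemporal monitoring
    data (such as contaminant concentrations sampled at groundwater wells) with
    tensor-product P-splines. The smoothing parameter is chosen through its
    closed-form marginal posterior under a conjugate normal-inverse-gamma model,
    either by maximum a posteriori selection or by model averaging, with
    classical selectors (AICc, GCV, BIC, observation- and well-based k-fold
    cross-validation) available for comparison. A one-time orthogonal
    decomposition makes the whole smoothing-parameter profile cheap to evaluate.
    Includes a finite-difference advection-diffusion plume simulator for
    generating realistic synthetic monitoring datasets and tools for scoring
    fitted surfaces against simulated truth by integrated squared error over
    the convex hull of the wells.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    splines,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
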