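Package: suturemorph
Title: Suture Complexity Metrics and Phylogenetic Comparative Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the geometric complexity of two-dimensional cranial
    suture traces with two independent metrics, the sinuosity index and a
    short-time Fourier transform power-spectral-density score, and relates
    complexity to locomotor mode, facial tilt, size and burrowing habit with
    phylogenetic comparative statistics. Provides equidistant semi-landmark
    resampling, generalised Procrustes superimposition with principal
    component analysis, Brownian-motion phylogenetic covariance tools with
    Pagel's lambda transforms and maximum-likelihood signal estimation,
    phylogenetic generalised least squares, simulation-based phylogenetic
    ANOVA, permutation-based multivariate shape regression, and a synthetic
    study generator for end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    phytools,
    nlme,
    jsonlite,
    optparse
Config/testthat/edition: 3
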