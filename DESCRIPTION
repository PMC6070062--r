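Package: canolux
Title: Stochastic Sunlit-Shaded Light Dynamics in 3-D Plant Canopies
Version: 0.1.0
Authors@R:
    person("canolux", "developers", email = "canolux@example.org", role = c("aut", "cre"))
Description: Tools for modelling the diurnal dynamics of direct light on leaf
    surfaces inside three-dimensional plant canopies. Triangle-mesh canopies are
    assembled from plant reconstructions (Wavefront OBJ), a clear-sky solar
    envelope and a periodic line-of-sight shading oracle produce per-patch light
    traces, and binary sunlit-shaded switching patterns are extracted from the
    traces. The switching dynamics are modelled as a two-state non-homogeneous
    Poisson process whose on and off rates depend on time of day and normalized
    height in the canopy; the package provides maximum-likelihood fitting of the
    rate functions, fast inversion-method simulation of realistic light
    patterns, principal-component summaries of fitted parameters across
    canopies, and a photoinhibition case study built on a non-rectangular
    hyperbola light-response model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
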