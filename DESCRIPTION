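Package: pollenvar
Title: Heat-Sum Pollen Emission Modelling and Variational Seasonal Source Inversion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale machinery for reconstructing the strength of tree pollen
    seasons from daily station counts. Implements the double-threshold heat-sum
    phenology and meteorology-modulated release model for alder, birch and olive
    pollen; a linear, adjoint-equipped two-dimensional advection-diffusion-
    deposition transport operator; an extended 4D-VAR assimilation of seasonal
    pollen integrals that estimates a per-cell multiplicative correction to the
    climatological pollen production, regularized by truncated iterations with an
    L-curve stopping rule; and a post-assimilation climatological bias
    recalibration based on radial-basis-function interpolation of station
    model-to-observation ratios. Synthetic meteorology, landscapes, station
    networks and observations allow the whole pipeline to run as an observing
    system simulation experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    geosphere,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
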