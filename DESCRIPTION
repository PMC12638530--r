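Package: spatdiet
Title: Spatiotemporal Diet and Predation-Index Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geostatistical generalized linear mixed models for predator
    biomass density and stomach-content relative prey mass, built on
    Matern Gaussian Markov random fields (SPDE finite-element
    discretization), Poisson-link delta-gamma and Tweedie observation
    families, breakpoint (hockey-stick) covariate effects, and AR(1) or
    random-walk time-varying coefficients.  Models are fitted by maximum
    marginal likelihood with the Laplace approximation (TMB).  Fitted
    models are projected onto a prediction grid with joint-precision
    uncertainty propagation to derive annual indices of per-capita and
    population-level predation and predator-prey spatial overlap (local
    index of collocation), together with a synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    TMB (>= 1.9),
    mgcv,
    interp,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: TMB, RcppEigen
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
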