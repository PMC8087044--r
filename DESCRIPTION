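Package: rametipm
Title: Integral Projection Models for Drone-Mapped Clonal Plant Demography
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits size-structured demographic models for clonal plants mapped
    as ramets (contiguous clonal units), such as invasive Carpobrotus mats
    surveyed by aerial imagery. Provides maximum-likelihood vital-rate
    regressions (logistic survival and flowering, Gaussian growth with an
    exponentially size-varying residual standard deviation, quasi-Poisson
    flower production, truncated-normal recruit sizes), AIC model selection
    among candidate forms, midpoint-rule discretisation of the integral
    projection kernel, asymptotic growth-rate and sensitivity/elasticity
    analysis at the kernel and sub-kernel level, bootstrap confidence
    intervals, and a parametric synthetic-data generator for testing and
    power analysis. Includes ground-truth size calibration for imagery-derived
    area measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
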