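Package: axondt
Title: Time-Dependent Axial Diffusion in Randomly Beaded Axons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward and inverse mapping between the varying cross-section
    of a tube (such as a beaded axon) and its time-dependent axial diffusion
    coefficient D(t) = Dinf + cD/sqrt(t). Implements arc-length profile
    geometry and tortuosity statistics, power-spectral-density plateau
    estimation for log cross-sectional fluctuations, closed-form
    effective-medium predictions of (Dinf, cD) and their power-law
    generalizations, a synthetic beaded-axon generator, a Fick-Jacobs
    random-walk simulation engine with an exact spectral oracle, 1/sqrt(t)
    regression of D(t) curves, and cohort statistics (nonparametric effect
    sizes and max-margin two-group projections) for separating injured from
    control axon populations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
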