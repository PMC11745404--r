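Package: borealstate
Title: Stochastic Tree-Cover Dynamics, Noise Separation and Forest-State
    Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs Langevin (drift-diffusion) models of boreal tree
    cover from panels of short annual time series: per-plot trends by the
    Theil-Sen estimator, a penalized cubic regression-spline drift per 0.5
    degree-Celsius temperature bin, and separation of process from
    observation noise by regressing lagged standard deviations on the
    square root of the lag. Fitted models are projected forward with the
    Euler-Maruyama scheme under optional warming-driven bin switching, and
    summarized as equilibria, density landscapes, mode shifts, and
    aboveground-biomass change via AIC-selected cover-biomass models. A
    synthetic-panel generator with known ground-truth dynamics supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
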