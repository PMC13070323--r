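Package: porpoisedsm
Title: Density Surface Models for Nearshore Harbor Porpoise Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end density surface modelling pipeline for nearshore
    line-transect surveys of harbor porpoise in an upwelling-driven eastern
    boundary current. Simulates a seeded synthetic coastal world and
    Marbled-Murrelet-design surveys with known truth; computes static habitat
    covariates (depth, distance to coast, shelf width, signed distance to
    capes, distance to estuaries, substrate) and dynamic upwelling covariates
    from daily coastal upwelling transport index series (10-day smoothing,
    spring transition, cumulative upwelling, relaxation events); fits
    multiple-covariate distance sampling detection functions with half-normal
    and hazard-rate keys and computes effective strip widths; fits stock-specific
    quasi-Poisson generalized additive models of porpoise counts with an
    effective-area offset and shrinkage term selection; predicts daily density
    over a coastal grid with ExDet extrapolation filtering; and relates annual
    density anomalies to upwelling phenology (STI, MAX, TUMI, LUSI) and
    basin-scale climate indices via interaction linear models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
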