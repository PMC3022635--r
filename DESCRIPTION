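Package: potaccess
Title: Potential Spatial Accessibility and Commuting-Based Exposure Indices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Gravity-based (potential) spatial accessibility indices for
    aggregated regional data. Calibrates generalized negative-exponential
    distance-decay functions from trip-length distributions by intercept-free
    log-linear regression over a grid of distance exponents or by nonlinear
    least squares, truncates the destination set at an empirically derived
    span, computes potential accessibility at points, at municipality
    administrative centres and on regular raster grids (written as ESRI ASCII
    grids), and extends the index to a commuting population by cumulating
    home and workplace potentials under a commute-length time-budget
    weighting averaged over origin-destination flows. Includes rank-based
    index comparison (Spearman) and a synthetic-region generator emulating
    skewed facility distributions and hub-dominated commuting flows, plus a
    command-line interface for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
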