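Package: fenflux
Title: Closed-Chamber Greenhouse-Gas Flux Budgets for Rewetted Peatlands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes growing-season carbon dioxide and methane budgets from
    closed-chamber concentration time series measured on permanent collars in
    peatlands. Provides ordinary least-squares chamber slope fitting with the
    quality-control rules used for static chambers (near-zero concentration
    ranges set to zero flux, non-linear series rejected on the r-squared of the
    linear fit), ideal-gas conversion of slopes to mass fluxes, partitioning of
    net ecosystem exchange into gross ecosystem productivity and ecosystem
    respiration, rectangular-hyperbola light-response and temperature-driven
    respiration model fitting with information-criterion model selection,
    hourly gap-filling and seasonal integration, trapezoidal interpolation of
    sparse methane campaigns, conversion to total carbon and 100-year global
    warming potential, vegetation cover-type classification and cover-weighted
    upscaling of collar budgets to sector means, and a synthetic-data generator
    with full truth bookkeeping for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
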