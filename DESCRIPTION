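Package: slfrisk
Title: Phenology and Climatic Suitability Mapping for the Spotted Lanternfly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A cohort-structured, raster-based degree-day model of the
    seasonal development of the spotted lanternfly (Lycorma delicatula),
    integrated with a climatic-suitability model based on cold- and
    heat-stress accumulation. Computes single-triangle degree-days with an
    upper threshold from daily minimum and maximum temperature grids, steps
    seven time-distributed cohorts through the univoltine life cycle (egg,
    nymph, pre-oviposition adult, ovipositing adult, first-generation egg),
    and maps five phenological events (egg hatch, nymphs halfway developed,
    adult emergence, oviposition, diapausing egg) as day-of-year rasters.
    Annual cold and heat stress units classify cells as unexcluded,
    moderately, or severely excluded, and multi-year runs are combined into
    potential-distribution maps. Includes a synthetic daily-climate
    generator, x-intercept regression for developmental thresholds and
    stage durations, a cohort-parameter grid search scored by
    overpredictions, MAE and bias, and validation tools for monitoring and
    single-encounter observations (regression with confidence and
    prediction intervals; one-sided paired Wilcoxon signed-rank tests;
    life-stage concordance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
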