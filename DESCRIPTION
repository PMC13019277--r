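Package: ch4flux
Title: Static-Chamber CH4 Flux Computation, Inhibition Partitioning and
    Seasonal Warming-Experiment Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing closed-chamber methane (CH4) flux
    measurements from long-term passive-warming (open-top chamber)
    experiments. Computes areal fluxes from 1 Hz closure curves by linear
    regression with a deadband, ideal-gas unit conversion and elevation /
    chamber-temperature adjustment; applies R-squared and 3-sigma quality
    control, replicate averaging and group-mean imputation; partitions net
    fluxes into gross soil production and two oxidation components using
    acetylene-inhibition closure pairs; computes seasonal treatment
    statistics (arcsinh standardization, Hedges'-corrected effect sizes,
    exact Wilcoxon signed-rank tests, percent change, Arrhenius Q10,
    quadratic soil-water-content response); processes sub-daily soil
    microclimate logger series into daylight growing-season means,
    snow-day classification and snowmelt dates; and includes a seeded
    synthetic-data generator with known ground truth so that every stage
    of the pipeline has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
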