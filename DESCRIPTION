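Package: thermomorph
Title: Thermal Physiology and Thermal Preference Analysis for Colour-Polymorphic Grasshoppers
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for analysing thermal physiology and
    thermal preferences in green-brown polymorphic grasshoppers. Processes
    radiant heat-up traces (internal thermocouple and external thermal-camera
    channels), thermal-gradient occupancy tracks with cubic
    position-to-temperature calibration, and reflectance spectra (300-1000 nm)
    with instrument-artefact correction and mean-brightness summaries.
    Inference uses a morph-constrained nonparametric bootstrap over whole
    individuals with percentile confidence intervals, for time-resolved
    difference and correlation curves as well as summary-statistic contrasts,
    plus a classical test-selection decision tree (t / Welch / Mann-Whitney,
    one-way ANOVA / Kruskal-Wallis with pairwise follow-up). A synthetic-data
    generator emulating the measurement design makes every stage testable
    without access to the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
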