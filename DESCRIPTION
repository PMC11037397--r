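Package: gaitcue
Title: Cued-Gait Experiments: Simulation, Gait-Parameter Extraction and
    Equivalence Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing cued-walking experiments on an instrumented
    walkway, as used to study visual cueing of gait in Parkinson's disease.
    Provides a synthetic-data generator for cued walking trials with known
    ground truth (speed, step-length and obstacle-crossing cues, plus headset
    head-pitch geometry), velocity-threshold stance detection, extraction of
    spatiotemporal gait parameters (gait speed, step length, crossing step
    length, head orientation), paired TOST equivalence tests with
    modulation-proportional bounds, split-plot repeated-measures ANOVA with
    Greenhouse-Geisser/Huynh-Feldt sphericity handling and partial
    eta-squared, Bonferroni post-hoc contrasts, and a pipeline that runs the
    full design end to end and writes report tables.
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
    car,
    ggplot2
Config/testthat/edition: 3
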