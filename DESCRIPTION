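Package: cochleaCI
Title: Intraoperative Electrocochleography and Cochlear-Implant Insertion
    Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of intraoperative extracochlear
    electrocochleography around cochlear-implant insertion in the guinea
    pig. Generates seeded synthetic cohorts of round-window recordings
    (compound action potential, cochlear microphonic, noise) across
    surgical conditions, extracts CAP thresholds with the two-times-baseline
    rule, computes threshold shifts and suprathreshold amplitude changes,
    models the cochlear spiral to convert electrode contact positions into
    insertion depth, percent basilar-membrane coverage and insertion angle,
    maps cochlear place to characteristic frequency (2.59 mm/octave and
    Greenwood forms), and reproduces the per-frequency nonparametric group
    comparisons and regressions of the study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
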