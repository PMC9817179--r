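Package: llpsfix
Title: Quantifying Fixation Artifacts in Liquid-Liquid Phase Separation Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how chemical fixation distorts the apparent
    liquid-liquid phase separation (LLPS) of proteins in cells. Implements a
    four-state mass-action model of fixation with an exact t = infinity
    solution and the delta-punctate-percentage artifact statistic, phase
    diagrams over equilibrium and rate ratios, quantification of LLPS image
    parameters (number of puncta by prominence-based maxima detection,
    surface roughness, punctate percentage via radial-slice FWHM disks),
    single-particle-tracking residence-time analysis with two-exponential
    survival fitting and photobleaching correction, seeded synthetic-data
    generators with ground truth, and nonparametric paired and unpaired
    statistics for live-versus-fixed comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
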