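Package: hairclamp
Title: Simulation and Analysis of Hair-Cell Patch-Clamp Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cellular electrophysiology of cochlear hair cells:
    a generative model of whole-cell membrane currents under ionic
    substitution and mechanical-stimulation protocols, and the analysis
    chain used to characterize a mechanotransduction-independent background
    leak conductance. Includes decomposition of background currents into
    leak and resting mechanotransducer components by NMDG and
    dihydrostreptomycin substitution, Hill dose-inhibition fitting with
    bootstrap confidence intervals, reversal-potential estimation and
    Goldman-Hodgkin-Katz permeability ratios with activity coefficients,
    unitary-channel amplitude estimation by Gaussian-mixture fitting of
    100 kHz sweeps, spike detection and excitability metrics under current
    clamp, and tonotopic aggregation with gradient tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
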