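Package: plateletwalk
Title: Stochastic Modelling of Shear-Induced Platelet Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the transverse transport of platelets in
    sheared blood from particle trajectories. Fits a piecewise
    exponential-bulk / power-law-tail distribution to platelet velocity
    magnitudes, solves its normalisation constraints, samples it exactly by
    inversion, and propagates platelets with a memory-time random walk
    between absorbing and reflecting walls. Includes estimators for the
    velocity autocorrelation function and its decorrelation time,
    mean-square-displacement diffusion coefficients with residency
    censoring, first-passage deposition curves, finite-size and parameter
    sensitivity scans, the Zydney-Colton reference diffusivity, and a
    synthetic-trajectory generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
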