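Package: issmri
Title: Tracer-Based MRI Quantification of Brain Interstitial-Space
    Microstructure and Interstitial-Fluid Clearance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses tracer-based magnetic resonance imaging
    studies of the brain interstitial space (ISS). A gadolinium tracer
    (Gd-DTPA) point-injected into deep grey matter spreads by hindered
    diffusion and is cleared from the interstitial fluid; the package
    generates MRI-like phantom time series from the porous-medium
    point-source diffusion-clearance model, converts signal increments to
    tracer concentration, fits the model by bounded nonlinear least squares
    to recover the effective diffusion coefficient D* and clearance rate
    constant k', derives tortuosity and clearance half-life, quantifies
    spreading-region volumes, and compares experimental groups with one-way
    ANOVA followed by Student-Newman-Keuls post-hoc tests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
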