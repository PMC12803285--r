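Package: tandemtimer
Title: Tandem Fluorescent Timer Analysis of Protein Trafficking and Turnover
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models, simulators and estimators for tandem fluorescent timer
    (tFT) experiments in epithelia. A fast-maturing (GFP-like) and a
    slow-maturing (Cherry-like) chromophore fused to the same protein report
    the age of the tagged pool through their fluorescence ratio. The package
    provides closed-form and ODE models of chromophore maturation under
    pulsed or constitutive synthesis with basolateral-to-apical trafficking,
    seeded generators of pulse-chase series and two-compartment wing-disc
    images with ground truth, image quantification operators (intensity
    profiles, compartment partitioning, puncta detection, intensity-weighted
    colocalization, membrane ratio extraction), calibration of maturation
    half-times from pulse-chase data, and inversion of Cherry/GFP ratios
    into residence-time estimates at basolateral membranes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
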