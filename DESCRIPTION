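Package: dcekin
Title: Physiological Compartment Modelling of Brain DCE-MRI Concentration Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward models and constrained nonlinear least-squares fitting
    for dynamic contrast-enhanced MRI (DCE-MRI) concentration-time curves in
    three brain pools: the blood pool, described by a slow-infusion arterial
    input function scaled by the hematocrit; four-compartment tissue voxels
    (blood, extracellular and intracellular extravascular spaces, and a
    water-inaccessible space) governed by Kety-Schmidt exchange kinetics;
    and two-compartment cerebrospinal-fluid (CSF) voxels fed by blood
    filtration. Provides the output-to-input flow (IOF) imbalance statistic
    that compares control-normalized mean CSF input and output rates across
    disease stages, a synthetic cohort and 4D phantom generator for
    validation studies, and a command-line interface tying the stages
    together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    optparse,
    RNifti,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
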