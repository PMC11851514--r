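Package: postmi
Title: Staged Simulation of Post-Myocardial-Infarction Tissue, Immune and
    Reactive-Oxygen Dynamics
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates left-ventricular remodeling after a myocardial
    infarction with a 14-state nonlinear ordinary differential equation
    model of cardiomyocytes, immune cells (neutrophils, monocytes, M1/M2
    macrophages, gamma-delta T cells), cytokines (IL-1, IL-10, IL-17),
    fibroblasts, collagen, stem cells and reactive oxygen species (ROS).
    Treatment is event-driven: an ischemic no-treatment stage is followed
    by oxygen restoration (which activates thresholded ROS-mediated
    ischemia-reperfusion damage) and an optional stem-cell bolus.
    Includes severity presets, a risk-factor/oxygenation/immune-activity
    multiplier grid, CSV/JSON input-output, a command-line interface, and
    a from-scratch extended Fourier Amplitude Sensitivity Test (eFAST)
    for global sensitivity analysis of the cardiomyocyte output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    parallel,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
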