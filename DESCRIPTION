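Package: dissectflow
Title: Windkessel Boundary-Condition Calibration and Haemodynamic Metrics
    for Aortic Dissection Flow Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating grouped three-element Windkessel (WK3)
    outlet boundary conditions of patient-specific aortic flow models and for
    post-processing the resulting haemodynamics. Derives per-outlet target
    mean flows from grouped 4D-flow measurements and literature minor-branch
    flows, transforms brachial cuff pressures to aortic inlet targets,
    simulates a parallel WK3 network driven by a periodic inflow waveform to
    cyclic periodicity, and tunes WK3 resistances and compliances so the
    network reproduces target flows and pressures. Includes rigid
    registration and temporal resampling of moving measurement planes, flow
    decomposition into forward and reverse components, transmural pressure,
    wall shear stress indices (TAWSS, OSI, ECAP), a Carreau-Yasuda blood
    viscosity model with a pulsatile transition criterion, Bland-Altman
    agreement statistics, and deterministic synthetic-data generators with
    closed-form ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    purrr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
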