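Package: fiberredox
Title: Fiber-Type-Specific Redox Autofluorescence Analysis of Skeletal
    Muscle Cross-Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the optical redox state of individual myofibers in
    multichannel immunofluorescence images of skeletal muscle cross-sections.
    Segments fibers, assigns myosin heavy chain (MHC) types by positivity
    rules with hybrid exclusion, measures background-subtracted NADH and
    flavoprotein (Fp) autofluorescence and the redox ratio Fp/(Fp + NADH),
    computes capillarization morphometrics (capillary density, capillary-to-
    fiber ratio, capillary contacts, sharing factor, oxygen diffusion
    distances) from distance-transform geometry, and fits linear mixed models
    with Tukey-adjusted pairwise contrasts across fiber type and time.
    Includes a synthetic-section simulator with planted ground truth, a
    cohort simulator for the inference layer, NADH calibration-series
    fitting, and dietary-plausibility (Goldberg/Black) and HOMA-IR screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    emmeans,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
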