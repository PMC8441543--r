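Package: octflow
Title: Depth-Resolved Particle Tracking Velocimetry for OCT Imaging of Sheared Fluids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring depth-resolved fluid velocity and shear rate
    from optical coherence tomography (OCT) B-mode image stacks of fluids
    sheared between microparallel plates. Includes closed-form Couette flow
    theory for triangle (constant shear rate) and sinusoidal (oscillatory
    shear) plate driving, a synthetic B-scan stack generator with ground
    truth for end-to-end validation, tilt/refraction preprocessing, grid-based
    normalized cross-correlation displacement tracking with depth-dependent
    frame decimation, sinusoid and weighted linear shear-rate fitting, and
    Bland-Altman agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
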