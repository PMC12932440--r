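Package: osteodyn
Title: Bone Remodeling Dynamics After Natural and Surgical Menopause
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ordinary differential equation model of a basic multicellular
    unit in bone, tracking preosteoblasts, osteoblasts, preosteoclasts,
    osteoclasts, osteocytes, sclerostin, and bone density through the
    menopausal transition. Estrogen decline is prescribed algebraically,
    either as a gradual hyperbolic decay (natural menopause) or as an abrupt
    exponential collapse to a low plateau (surgical menopause following
    bilateral oophorectomy), with transient post-surgical increases in
    osteocyte apoptosis and osteoclast differentiation. Provides closed-form
    premenopausal steady states, adaptive Runge-Kutta simulation of bone
    mineral density trajectories, bound-constrained Levenberg-Marquardt
    calibration against normalized cross-sectional BMD series, parameter
    sensitivity envelopes, a sclerostin-production sweep of steady bone
    density change rates, a curation pipeline for published BMD study
    tables, and a synthetic-cohort generator for parameter-recovery
    experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    lhs,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
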