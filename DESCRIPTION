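Package: fmgstack
Title: Two-Stage Stacked Regression for Multi-DoF Isometric Force and
    Torque Estimation from Force Myography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating multi-degree-of-freedom isometric hand
    force and torque from multi-channel force-myography (FMG) band
    recordings. Provides a protocol-structured synthetic data generator
    (focused-axis sinusoidal and free-exertion sessions, band-dependent
    nonlinear sensor coupling with drift, noise and trial gain
    variation), the preprocessing chain (Butterworth high-pass, FIR
    low-pass, train-referenced min-max normalization), derivative and
    spherical-coordinate feature augmentation, a generalized regression
    neural network (GRNN) implemented from its kernel-average definition
    alongside nu-SVR and random-forest stage-1 learners, a two-stage
    stacking scheme with a multi-output GRNN second stage, cross-trial
    (leave-one-trial-out) R-squared evaluation over all band
    combinations, and two-way ANOVA with Tukey HSD post-hoc comparison
    of band placement and algorithm effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    randomForest,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
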