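Package: corneomech
Title: Depth-Resolved Stiffness Tomography of Corneocytes from AFM Force
    Volumes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of atomic force microscopy (AFM) force-volume data
    from stratum corneum corneocytes. Implements the Hertz-Sneddon contact
    model for pyramidal tips, force-curve preprocessing (baseline
    correction, contact-point detection, deflection-corrected indentation),
    depth-resolved estimation of the apparent elastic modulus in 5 nm
    indentation windows ("stiffness tomography"), per-cell and per-subject
    aggregation, and cohort-level statistics: Shapiro-Wilk normality
    reporting, variance-gated Student/Welch two-group comparisons,
    genotype-stratified comparisons, Spearman correlation matrices with
    exact small-sample permutation p-values, and ordinary least-squares
    regression. A synthetic-data module generates force volumes from
    layered depth profiles and study cohorts with known ground truth so the
    whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
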