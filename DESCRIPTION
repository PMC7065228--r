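Package: mamsadapt
Title: Adaptive Multi-Arm Multi-Stage Clinical Trial Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design and simulation of adaptive multi-arm multi-stage (MAMS)
    clinical trials in which several treatments are compared pairwise with a
    common control over successive analyses.  Implements group-sequential
    efficacy boundaries for the maximum of correlated score statistics,
    closed testing with exact Dunnett (multivariate t), Bonferroni and Simes
    multiplicity-adjusted p-values, conditional-error-preserving boundary
    recomputation after treatment selection and sample-size re-estimation
    (the cumulative MAMS procedure), inverse-normal combination of stage-wise
    adjusted p-values (the stage-wise MAMS procedure), exact analytic power
    for the two-dose no-early-stopping case, single-stage Dunnett power and
    sample size, and a patient-level Monte Carlo engine for operating
    characteristics (power, family-wise error rate, average sample size).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    mvtnorm,
    statmod,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
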