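Package: fasdprev
Title: Selection-Rate-Adjusted Prevalence Estimation for Multi-Phase
    Screening Studies of Fetal Alcohol Spectrum Disorder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for active-case-ascertainment prevalence studies that
    screen a population in successive phases and diagnose only the
    children who advance through every phase.  Implements the
    selection-rate-adjusted plug-in prevalence estimator for FAS, pFAS,
    ARND and total FASD (per 1000 children), a screen-negative
    extrapolation sensitivity analysis, Monte Carlo percentile confidence
    intervals that resample every stage proportion and case count, the
    contingency and mean-comparison statistics used for case/control
    group comparisons, and a child-level synthetic cohort simulator with
    configurable screening sensitivity and per-stage attrition so the
    whole pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
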