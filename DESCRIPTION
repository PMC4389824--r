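Package: etiohet
Title: Age-Related Etiologic Heterogeneity Diagnostics for Cox Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing age-related etiologic heterogeneity
    (nonproportional hazards) in prospective cohort time-to-event data: a
    multiplier-resampling supremum test on the cumulative score process, the
    Grambsch-Therneau scaled Schoenfeld residual test with smoothed beta(t)
    curves, and restricted cubic spline time-by-covariate interaction Cox
    models with hierarchical association/nonconstancy/nonlinearity tests and
    hazard-ratio-over-time curves, for both fixed and time-varying
    covariates.  Includes a counting-process Cox partial likelihood engine
    with delayed entry and Breslow/Efron ties, and a simulator of
    visit-based prospective cohorts with staggered entry, detection-time
    events, and left-censoring for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
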