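Package: nvhap
Title: Electronic Surveillance and Attributable Mortality of
    Non-Ventilator Hospital-Acquired Pneumonia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-level surveillance of non-ventilator
    hospital-acquired pneumonia (NV-HAP) from routine electronic health
    record data. Implements a fully electronic NV-HAP surveillance
    definition (sustained oxygenation deterioration after a stable
    baseline, plus abnormal temperature or white blood cell count, chest
    imaging, and a new multi-day antimicrobial course), descriptive
    incidence reporting with Wilson confidence intervals, chart-review
    validation statistics (positive predictive value, Cohen kappa), and
    estimation of the inpatient mortality attributable to NV-HAP via
    daily propensity scores, inverse-probability weights, and a weighted
    Aalen-Johansen estimator of the cumulative incidence of inpatient
    death versus alive discharge under current care and under
    hypothetical elimination of NV-HAP, with clustered bootstrap
    confidence intervals, stratified analyses, and multi-site pooling.
    Includes a synthetic multi-facility inpatient-trajectory generator
    with known onset and outcome hazards for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    e1071,
    glmnet,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
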