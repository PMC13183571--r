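Package: gaitmcid
Title: Reliability and Minimal Clinically Important Differences of
    Spatiotemporal Gait Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating quantitative gait endpoints in clinical
    cohorts with sensory ataxic gait, such as chronic peripheral
    vestibulopathy. Reads step-level footfall tables from instrumented
    walkways, extracts thirteen spatiotemporal gait metrics across the
    pace, phase, variability, asymmetry and postural-control domains,
    quantifies test-retest reliability with two-way intraclass
    correlation coefficients (consistency and absolute-agreement forms,
    with F tests and confidence intervals), and estimates minimal
    detectable change (MDC95) together with distribution-based,
    anchor-based and triangulated minimal clinically important
    differences (MCID) against clinical anchors (Functional Gait
    Assessment, Falls Efficacy Scale-International, SF-12 Physical
    Component Score). Includes a seeded synthetic-cohort generator at
    both the footfall-event and metric level for validation and power
    exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
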