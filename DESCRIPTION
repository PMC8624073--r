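Package: ghrelkit
Title: Test-Retest Reliability Analysis of Gastrointestinal Hormone Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying the test-retest reliability of repeated
    biomarker measurements, built around fasting gastrointestinal hormone
    panels (ghrelin, leptin, GLP-1, pancreatic polypeptide) assessed at
    baseline and follow-up. Implements the absolute-agreement intra-class
    correlation ICC(A,1) with F-based confidence intervals and Koo-Li
    reliability categories, covariate-adjusted ICC from random-intercept
    mixed-model variance components with a parametric bootstrap, Monte Carlo
    paired permutation tests with an exact sign-flip oracle, ELISA
    detection-limit and upper-standard censoring rules, dietary-habits and
    physical-activity index scoring, a seeded synthetic cohort generator
    with controllable true ICC per hormone, and an end-to-end analysis
    pipeline emitting tabular and forest-plot-ready reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
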