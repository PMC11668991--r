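Package: emaqc
Title: Data-Quality Evaluation for Ecological Momentary Assessment Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate the quality of ecological momentary assessment
    (EMA) data: participation and compliance metrics with covariate-adjusted
    logistic and Poisson regression models, decomposition of momentary affect
    variance into between- and within-person components with intraclass
    correlations, multilevel (generalizability-theory) between-person and
    within-person reliability coefficients and per-person raw Cronbach alpha,
    and detection of careless responses (fast responding, straight-lining,
    psychometric-antonym threshold curves) and careless responders
    (minimum-valid-assessment stability rule and individual-reliability rule).
    Includes a seeded synthetic EMA cohort generator emulating a 14-day,
    4-prompts-per-day design with 12 Likert items per prompt, so the whole
    pipeline is testable end to end without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
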