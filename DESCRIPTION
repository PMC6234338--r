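Package: cogbattery
Title: Engines, Cohort Simulation and Analysis for a Gamified Cognitive
    Test Battery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Headless, scriptable engines for a five-task gamified
    cognitive battery (action acquisition, four-choice vigilance, mental
    rotation, 2-back working memory, and multiple object tracking) with
    exact scoring rules, scoring and classification for the reduced
    Morningness-Eveningness Questionnaire, a synthetic participant and
    cohort simulator with demographics, chronotype, attrition and
    practice effects, and the cohort-analysis pipeline (adherence
    filtering, outlier trimming, gender ANCOVA with an engagement
    covariate, age-stratified ANOVA, correlation and practice-curve
    summaries). Session records round-trip through a versioned JSONL or
    tidy CSV schema, and a small command-line interface ties simulation
    to analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
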