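Package: trialcea
Title: Trial-Based Effectiveness and Cost-Effectiveness Analysis for
    Two-Arm Repeated-Measures RCTs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for trial-based economic
    evaluation of a two-arm randomized controlled trial with repeated
    psychometric outcomes: seeded synthetic trial generation, multiple
    imputation of follow-up scores under missing-at-random dropout with
    Rubin's-rules pooling, generalized estimating equations with an
    exchangeable working correlation and robust (sandwich) standard errors,
    Bonferroni-adjusted between-group contrasts with Cohen's d and
    half-SD minimal important difference flags, a societal cost model
    (amortized fixed program costs, direct medical costs, human-capital
    indirect costs), quality-adjusted life years by the area-under-the-curve
    method, and a stratified nonparametric bootstrap cost-effectiveness
    evaluation producing ICER, net monetary benefit, bias-corrected and
    accelerated intervals, cost-effectiveness plane quadrants, and
    cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    ggplot2,
    stats,
    tools,
    utils,
    yaml
Suggests:
    boot,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
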