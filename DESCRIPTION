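Package: doorstats
Title: Desirability of Outcome Ranking (DOOR) Analysis for Clinical Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rank-based and grade-based benefit:risk analysis of two-arm
    clinical studies using the desirability of outcome ranking (DOOR)
    paradigm. Estimates the DOOR probability (the tie-adjusted
    Wilcoxon-Mann-Whitney win probability) with tie-corrected confidence
    intervals and hypothesis tests, overall, cumulative and per-component;
    partial-credit (grading-key) comparisons of mean grades with grading-key
    grids and tipping boundaries; distribution and expected gain/loss tables
    standardized per 1,000 patients; inverse-probability-of-treatment
    weighted variants with stratified bootstrap intervals for nonrandomized
    comparisons; design-stage power simulation and sample-size search; and a
    reproducible synthetic trial generator including a confounded scenario
    for validating the weighted estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
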