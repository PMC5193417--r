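Package: hivebeat
Title: Colony-Level Analytics for Continuous Hive Monitoring and Cage Bioassays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing continuous honey bee hive monitoring data and
    cage bioassays from pesticide field trials. Decomposes hive-scale weight and
    internal-temperature series into a 25-hour running-average trend and
    within-day residuals, estimates daily activity by fitting 24-hour sine
    curves to 3-day windows of detrended data, detects behavioural episodes
    (nectar flows, robbing events) from daily and sub-daily weight dynamics,
    fits right-censored Weibull survivorship models to cage mortality with
    per-bee-day consumption accounting, computes inspection-derived colony
    metrics (hexagon-grid brood area, Varroa infestation rates, feed
    accounting, dose-unit conversion), and compares treatment groups with
    covariate-adjusted ANOVA, Bonferroni post hoc contrasts and nonparametric
    tests. A synthetic-data generator emulates every input family with known
    ground truth so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
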