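Package: farmgrade
Title: Pig Grouping and Farm Management Grading from Carcass Weight and Backfat
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Groups slaughter pigs by absolute z-scores of carcass weight and
    backfat thickness using a from-scratch k-means (k-means++ seeding, Lloyd
    iterations, k = 9), maps the nine clusters to four uniformity groups,
    classifies carcasses under the Korean meat-quantity grade bands (1+/1/2),
    assigns each farm a Management Grade (A-D) by pushing its mean carcass
    weight and backfat through the fitted model, and fits per-group linear
    regressions of five primal-cut weights on carcass weight and backfat.
    Includes a calibrated synthetic-herd generator with farm-level effects so
    the whole pipeline is testable without auction data.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
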