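Package: modact
Title: Engagement-Anchored Analysis of Wearable Physical Activity Around
    Digital Intervention Module Visits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs visits to digital behavior-change intervention
    modules from enter/leave log events, classifies visit completion by a
    minimum-fraction-of-estimated-duration rule, builds event-anchored 7-day
    and weekly windows of wearable daily activity summaries (with a
    step-count wear-day filter and a minimum-valid-days rule), and tests
    immediate and 8-week sustained before/after effects with Wilcoxon
    signed-rank tests (exact and tie-corrected normal approximation).
    Includes a seeded synthetic-cohort generator with ground truth so every
    pipeline stage is verifiable without trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
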