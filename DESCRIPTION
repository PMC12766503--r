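Package: screensift
Title: Duplicate Detection and Enrollment Quota Control for Remote Study Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An auditable screening-integrity engine for decentralized and
    other remotely recruited studies. Flags potential duplicate (and thereby
    potentially fraudulent) screening-survey submissions using configurable
    exact-match criteria (OR across criterion blocks, AND within a block)
    restricted to a time window; groups matching submissions into transitive
    duplicate sets and classifies originals versus duplicate entries;
    enforces enrollment minimums and maximums (count or percent, full-sample
    or blocked, optionally nested across several characteristics) with
    reserved-slot logic; and ships a seeded synthetic screening-stream
    simulator with ground-truth labels so detection and quota behavior can
    be evaluated without any real participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
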