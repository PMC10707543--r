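Package: fitindex
Title: Hierarchical Physical-Fitness Evaluation Index Systems for Elite Athletes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and applies hierarchical physical-fitness evaluation
    index systems for elite athlete cohorts. Covers the full workflow:
    Delphi expert-consensus screening of candidate indexes, R-type
    (variable) hierarchical clustering with coefficient-of-determination
    representative selection, expert-derived summation-normalization
    weighting, percentile-based five-band scoring standards, three-stage
    weighted composite scoring and rating, general and ideal fitness
    models, and validation statistics (exact r-by-c contingency test by
    full enumeration, Kendall tau-b test-retest reliability). Includes a
    synthetic-cohort generator with block correlation structure and the
    published freestyle-skiing-aerials reference system as bundled
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
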