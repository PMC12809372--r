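Package: nhobs
Title: Observable Medication Use Time for Nursing-Home Residents in
    Linked Administrative Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constructs nursing-home episodes from Minimum Data Set style
    tracking and assessment records, expands them to a resident-day grid,
    flags each day for fee-for-service Medicare enrollment (Parts A, B and
    D without managed care), post-acute skilled-nursing coverage, and
    inpatient hospitalization, and extracts maximal contiguous runs of
    "observable medication use time" - days on which prescription
    dispensings can appear in Part D claims. Includes a linked synthetic
    claims generator, stepwise attrition accounting by time-since-admission
    bins, a configurable day-count long-stay comparator, monthly algorithm
    comparisons, point prevalence of a drug class within observable time,
    a partition-invariant end-to-end pipeline, and a command-line front
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
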