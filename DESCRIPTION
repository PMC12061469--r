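Package: callvar
Title: Multi-Level Variation Analysis of Anuran Advertisement Calls
Version: 0.1.0
Authors@R: person("callvar", "developers", role = c("aut", "cre"),
    email = "callvar@example.org")
Description: A tested pipeline for quantifying variation in frog
    advertisement calls at multiple biological levels. Extracts six
    standard call parameters (call duration, call interval, dominant
    frequency, 5-95% bandwidth, pulse number, pulse rate) from audio
    recordings using algorithmic call segmentation and pulse detection;
    computes within-individual, among-individual, among-population and
    between-group coefficients of variation with Gerhardt's
    static/intermediate/dynamic classification and discriminability
    ratios; fits temperature regressions and applies the Platz-Forester
    correction to a common reference temperature; runs Mantel permutation
    tests of isolation by distance; and compares geographic groups with a
    distribution-driven test-selection procedure. Includes a synthetic
    call and measurement-table generator with known ground truth so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
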