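Package: enrichcost
Title: Cost-Efficient Enrichment Trial Design with One- and Two-Stage Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design tools for randomized trials that enroll only subjects whose
    baseline symptom severity exceeds a threshold, when the treatment effect
    interacts with baseline severity. Computes the marginal treatment effect
    among enrollees from truncated-normal moments, approximates the power of
    the marginal two-sample test, inverts it for the required sample size, and
    finds the severity threshold(s) minimizing total trial cost under a
    one-stage screening procedure or a two-stage procedure that prescreens on
    a cheap surrogate measurement before on-site screening. Designs are
    verified by seeded Monte-Carlo simulation of the full
    recruit-randomize-test pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
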