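Package: treking
Title: Time-Resolved Kinase Regression and Phosphosignaling Network Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts real-time impedance (cell-index) screens of
    kinase-inhibitor-treated cell monolayers into time-resolved predictions of
    kinase barrier functionality. Normalized cell-index kinetics are reduced to
    sliding-window areas under the curve, regressed per window against an
    inhibitor x kinase residual-activity panel by elastic-net regularization
    (time-resolved kinase regression, tKiR), and the resulting kinase
    functionality profiles are clustered on a self-organizing map and assembled
    into local phosphosignaling networks as unions of all shortest paths over a
    kinase-substrate background graph. Includes a seeded synthetic-screen
    generator with planted ground truth for end-to-end benchmarking, and the
    validation-side quantification rules (densitometry fold changes,
    activation calls, relative qPCR expression).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    glmnet,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
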