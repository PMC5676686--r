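Package: tdl
Title: Transcriptomics-Driven Lipidomics Target Prediction and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts a condition-specific altered lipidome from two-group
    differential gene expression through three branches (a lipid-gene
    annotation database, a lipid-relevant pathway database, and a genome-scale
    metabolic model), merges the branches into a consensus measurement panel
    with negative-control lipid classes, and evaluates the panel against a
    measured lipid table using two-sample Kolmogorov-Smirnov tests with
    Benjamini-Hochberg false-discovery-rate control and a six-category
    prediction-versus-observation scoring grid. Includes seeded synthetic-data
    generators (toy metabolic models, two-group expression with planted
    effects, lipid tables with planted class shifts) so the whole pipeline is
    testable offline, readers for SBML Level 3 + FBC and a tabular metabolic
    model dialect, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
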