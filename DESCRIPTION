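Package: setquery
Title: Query Annotated Expression Compendia by Gene-Set Activity Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes weighted gene-set activity scores across large
    compendia of consistently normalized expression samples, selects
    samples matching a user-specified activity pattern of interest
    (numeric cutoffs, interval unions, polygons in activity space, or
    formula predicates), and reports the biological contexts enriched
    among the selected samples using one-sided Fisher's exact tests with
    Bonferroni correction and pseudocounted fold changes. Includes
    weighted gene-set and GMT parsers, cross-species homolog conversion,
    gene-set noise perturbation for robustness studies, a seeded
    synthetic-compendium generator, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    grDevices,
    graphics,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'activity.R'
    'cli.R'
    'compendium.R'
    'enrichment.R'
    'genesets.R'
    'poi.R'
    'poi-io.R'
    'utils.R'
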