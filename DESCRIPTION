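Package: csfsub
Title: Co-Expression Network Subtyping of CSF Proteomic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for cerebrospinal-fluid (CSF) proteomic
    subtyping from multi-batch tandem-mass-tag (TMT) cohorts: iterative
    median-polish harmonization of abundance ratios (TAMPOR) with bootstrap
    batch/set regression, weighted co-expression module discovery (biweight
    midcorrelation, signed adjacency, topological overlap, dynamic branch
    cutting, eigenproteins and kME), modularity-based clustering of samples
    into proteomic subtypes on a hub-protein similarity graph with
    replicate-pair validation, cross-cohort subtype transfer by supervised
    embedding with nearest-centroid assignment, mean-centered subtype
    signature correlation, and plasma-dilution module-response statistics.
    A synthetic cohort generator with planted modules, subtypes, batch
    structure and technical replicates provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    uwot,
    mclust
Config/testthat/edition: 3
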