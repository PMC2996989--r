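Package: sensepi
Title: Sensitivity-Based Epistatic Analysis of Growth Phenotypes in Two
    Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative genetic interaction mapping from replicate growth-rate
    measurements of a wildtype plus single- and double-deletion library assayed
    in two environments (e.g. rich medium with and without a DNA-damaging
    drug). Implements fitness-based (F), environmental-sensitivity (ES) and
    sensitivity-based (S) epistasis scores under multiplicative neutrality,
    parametric-bootstrap significance testing, environment assignment of
    interactions, evidence-set enrichment, directional phenotypic-masking
    detection within declared complexes, hierarchical clustering of interaction
    profiles, and a synthetic-library generator with planted interactions for
    validation. Exponential growth rates are estimated from optical-density
    time courses by log-linear least squares within a configurable fit window.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
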