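Package: cortexcomp
Title: Optimal Volume Composition of Cortical Gray Matter
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the fractional volume composition of cortical gray matter
    (axons, dendrites, dendritic spines, glia/astrocytes, capillaries) as the
    outcome of evolutionary optimization. Implements six spine-size
    distribution families with closed-form threshold-exceedance
    probabilities, geometric-probability and minimal-spanning-tree coupling
    laws linking the five fractions, constrained optimization of
    wire-minimization, spine-economy-maximization and mixed meta-principle
    fitness functions, Euclidean and Mahalanobis model-data distances against
    a built-in cross-species composition table, allometric log-log scaling
    analysis, parameter sweeps, and synthetic-data generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
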