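Package: treemed
Title: Phylogeny-Guided Mediation Analysis for Microbiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tests whether a microbial community mediates the effect of a
    treatment on an outcome by fitting an independent log-ratio subcomposition
    mediation model at every internal node of a rooted phylogenetic (or
    taxonomy) tree. Node-level p-values for the composite no-mediation null
    are computed from a three-component mixture whose weights are estimated
    across nodes by an empirical characteristic function method, with
    alternative p-value distributions estimated by the Grenander decreasing
    density estimator. Mediating clades are detected by Benjamini-Hochberg
    selection and a community-level test is obtained by the harmonic mean
    p-value combination. A synthetic-data generator reproduces the design of
    the accompanying simulation studies, so the method can be exercised and
    calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
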