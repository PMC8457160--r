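Package: dendrodiel
Title: Diel Stem-Growth Analysis of Dendrometer Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Partitions high-resolution point-dendrometer stem-radius series
    into irreversible radial growth (GRO) and tree water deficit (TWD) with
    the zero-growth rule, derives hourly-resolved diel growth statistics
    (relative contribution to annual growth, growth probability, hourly
    growth rates) through a nested tree / site-species / species aggregation,
    relates growth to vapour pressure deficit and soil water potential
    (regressions, binned loess response surfaces, bootstrap coefficient-of-
    variation uncertainty grids, main-growth envelopes), and runs the
    cross-species regressions of diel peak-growth timing against annual
    growth hours and annual increment. Includes a synthetic-forest generator
    with ground-truth growth for offline validation of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    zoo,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
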