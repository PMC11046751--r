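Package: seasonlap
Title: Seasonal Predator-Prey Spatial Overlap from GPS Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how the spatial overlap between a
    territorial predator and its migratory ungulate prey changes across
    seasons, from raw GPS collar relocations. Includes a synthetic track
    generator (Ornstein-Uhlenbeck home-range movement with corridor
    transits), track regularization and anomaly censoring (speed, first
    passage time, turning angle, post-mortality runs), movement-strategy
    classification and migration-timing quartiles, Brownian bridge
    movement model occurrence distributions on a shared planar grid,
    hierarchical population-level seasonal distributions and a migration
    corridor, a mechanistic range-shift likelihood test, and
    logit-linear overlap models with exact Mann-Whitney comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
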