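Package: ethoscreen
Title: Trajectory-Based Behavioral Screening of Inhalation Toxicity in Drosophila
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computational ethology toolkit for inhalation-toxicity screening
    with walking flies in a vertical arena. Provides a data model for
    fixed-rate 2-D movement tracks, a calibrated correlated-random-walk
    simulator of strain-by-treatment cohorts, segment-wise kinematic
    parameter extraction (speed, acceleration, locomotory rate, meander,
    stop duration, slipping number), zone-occupancy accounting,
    box-counting fractal dimension of movement tracks, self-organizing map
    classification of movement segments with Ward clustering of the
    codebook into an ethogram of four movement patterns, and group
    summary reporting with Pearson correlation structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
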