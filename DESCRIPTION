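Package: phenoseg
Title: Change-Point and Trend Analysis of Phenological and Temperature Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Retrospective analysis of short annual series of flowering dates
    and of mean temperatures during chill-accumulation (CA) and
    heat-accumulation (HA) periods. Fits homoscedastic Gaussian multiple
    change-point models (piecewise constant and piecewise linear) by dynamic
    programming, selects the number of segments with a modified Bayesian
    information criterion (mBIC), compares model families with Jeffreys' rule,
    and quantifies segmentation uncertainty through the posterior distribution
    of change-point locations obtained by exhaustive enumeration of
    segmentations. Includes aggregation of daily temperature records into
    CA/HA period means, flowering-duration and flowering-temperature
    correlation analyses, and seeded synthetic-data generators emulating
    temperate and mild-climate phenological regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
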