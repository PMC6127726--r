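Package: capuff
Title: Detection and Quantal Analysis of Ca2+ Puffs in TIRF Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and quantifying local Ca2+ release events
    (Ca2+ puffs) in total internal reflection fluorescence (TIRF) microscopy
    time series. Implements baseline normalization of image stacks to
    per-pixel z-like units, threshold-cluster event detection in space-time,
    sub-pixel localization by 2D Gaussian fitting, puff kinetics (20-100%
    rise, 100-20% decay, duration at half-maximal amplitude), quantal
    analysis of stepwise channel closures during the falling phase,
    active-channel counting from the unitary fluorescence step, assignment
    of puffs to fixed release sites, and saturation statistics for the
    discovery of new release sites. A synthetic-movie generator with ground
    truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    tiff,
    EBImage,
    igraph,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
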