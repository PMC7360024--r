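Package: vrtracker
Title: Closed-Loop Virtual-Reality Animal Tracking and Behavioral Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hardware-free re-implementation of a closed-loop single-animal
    tracker and virtual-sensory-reality engine for small model organisms
    (Drosophila larvae and adults, zebrafish larvae). Provides automatic
    animal detection with background reconstruction, per-frame local
    background-subtraction tracking inside a moving region of interest,
    skeleton-endpoint head/tail classification, parametric virtual sensory
    landscapes (Gaussian, exponential, volcano, checkerboard, raster) with a
    configurable stimulus lag, the full trajectory-analysis pipeline
    (triangular/boxcar smoothing, speed, relative sensory experience,
    distance to source, preference index, swim-bout segmentation, turn-angle
    and turn-index statistics, trial-inclusion filters), and a seeded
    synthetic-arena generator producing ground-truthed agent trajectories
    and rendered videos so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    png,
    tiff,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
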