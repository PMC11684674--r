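Package: embryostager
Title: Quantitative Staging and Morphometrics for Medfly Embryogenesis
    Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying embryonic development of the
    Mediterranean fruit fly (Ceratitis capitata) from nuclear-labelled
    fluorescence time-lapse recordings. Implements embryo length dynamics
    from z-maximum projections (adaptive local-mean thresholding and
    convex-hull extent), blastoderm nuclei area and density in a posterior
    analysis window (multi-scale Laplacian-of-Gaussian seeding and a
    deterministic seeded immersion watershed), three-dimensional pole-cell
    nucleus counting in anisotropic stacks, germband-tip migration
    kinematics, and a two-level developmental staging model (six
    embryogenetic events spanning seventeen stages) with cross-dataset
    duration statistics. A synthetic-data generator produces calibrated
    frames, stacks and staging tables with exact ground truth for testing
    and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Rcpp,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
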