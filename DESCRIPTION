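Package: spherosect
Title: Quantitative Image Analysis for Cryosectioned Spheroid and Hydrogel Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Morphometry and quantification tools for thin-section imaging of
    multicellular spheroids embedded in fibrillar hydrogels. Implements apparent
    fiber-width measurement by Gaussian cross-section fitting with an adjusted-R^2
    acceptance rule, characteristic pore-size estimation from exponential fits to
    row/column gap statistics of binarized network images, a single-molecule
    localization microscopy (SMLM) reconstruction chain (detection, Gaussian
    fitting, photon and sigma filtering, DBSCAN outlier removal, cross-correlation
    drift correction, normalized-Gaussian rendering) with localization-precision
    and Nyquist resolution estimates, spheroid staining and invasion metrics,
    mass-spectrometry-imaging intensity statistics with ppm-tolerance annotation,
    and intensity-based rigid registration for correlative imaging. A synthetic
    phantom generator with full ground truth makes every estimator testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
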