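Package: rodtrack
Title: Single-Particle Tracking and Morphometrics for Rod-Shaped Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification pipeline for the membrane dynamics of bacterial
    cell-wall synthesis machinery imaged by TIRF microscopy. Detects
    diffraction-limited foci with a Laplacian-of-Gaussian filter, links them
    into trajectories by linear-assignment matching, classifies tracks as
    directed or diffusive from mean-squared-displacement fits, estimates
    per-trajectory diffusion coefficients from the cumulative distribution of
    displacement magnitudes, and decomposes the resulting coefficient
    distribution into two log-normal subpopulations by maximum likelihood.
    Also computes rod-cell curvature descriptors (solidity, lateral and
    longitudinal asymmetry, width variation) from cell contours, and ships
    synthetic-data generators (trajectories, TIRF-like image stacks, bent-rod
    contours) with known ground truth for validating every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    mgcv,
    tiff,
    jsonlite,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
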