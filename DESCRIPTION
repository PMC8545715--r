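Package: poretomo
Title: Pore Structure and Multifractal Analysis of X-Ray Microtomography Volumes
Version: 0.1.0
Authors@R: person("poretomo", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Characterizes micrometer-scale pore structure in porous carbons
    (e.g. softwood-pellet biochar) from 3D X-ray microtomography volumes.
    Provides TIFF stack input/output, grayscale quantization and threshold
    segmentation with largest-solid-component retention and centered ROI
    cropping, 3D connected-component pore-network metrics (total porosity,
    largest-pore connectivity fraction, surface-to-volume ratios), per-axis
    pore frequency curves, and 1D multifractal analysis (Chhabra-Jensen
    singularity spectrum and Renyi generalized dimensions) via dyadic
    partitioning and log-log regression, used to test homogeneity and
    isotropy of the pore distribution. Includes a synthetic phantom
    generator (fragment packings, tube arrays, binomial cascades) so the
    whole pipeline is testable without beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
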