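Package: gasigmap
Title: Quantitative Mapping of Gibberellin Signaling in the Shoot Apical Meristem
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative image analysis of ratiometric hormone-signaling
    biosensors in the Arabidopsis shoot apical meristem (SAM). Provides 3D nucleus
    detection and ratiometric quantification of a degradation-based GA signaling
    sensor (signaling read out as 3 minus the sensor/reference intensity ratio),
    3D watershed cell segmentation from a cell-wall stain, L1 layer extraction and
    surface curvature estimation, rigid temporal registration and lineage-based
    surface growth and growth-anisotropy measurement, division-plane angle
    statistics relative to the meristem radial axis, and population-scale atlas
    averaging of multiple meristems aligned on the stem-cell (CLV3) domain. A
    synthetic meristem image generator with full ground truth makes every stage of
    the pipeline testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
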