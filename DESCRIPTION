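Package: echowrap
Title: Lesion-Size Sensing from B-Mode Ultrasound Stacks of a Conformal Hyperechoic Shell
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates serial B-mode ultrasound slice stacks of a hyperechoic
    microrobotic shell wrapped over hemispherical lesions, segments the bright
    shell in each slice, reconstructs a 3D point cloud in millimetres, and
    estimates the wrap curvature radius by constrained local PCA sphere fitting
    or a global algebraic sphere fit. Includes error metrics and longitudinal
    trend analysis for monitoring lesion size over repeated scans, plus
    plain-text stack, point-cloud and report I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
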