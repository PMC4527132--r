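Package: srseg
Title: Automated Segmentation of Super-Resolution Microscopy Images by
    Controlled Gaussian Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments super-resolution (STED/SMLM) microscopy images into
    biologically meaningful objects by controlled Gaussian fusion of
    nanoscopic clusters, maximum correlation thresholding (MCT), watershed
    declumping by shape or local intensity maxima, and parent-child object
    relation to count clusters per domain (for example gp210 subunits per
    nuclear pore complex).  Ships a parametric two-color STED-like nuclear
    pore simulator and an SMLM-like active-zone simulator with full ground
    truth, preset analysis pipelines, preprocessing comparison (3x3 mean
    smoothing, difference-of-Gaussians bandpass), CSV/TIFF input-output and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    tiff,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
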