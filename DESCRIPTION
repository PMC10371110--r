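Package: fgsim
Title: Simulation and Image Processing for Wearable Fluorescence-Guided
    Surgery Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and process dual visible/near-infrared (NIR)
    image streams of the kind produced by head-mounted fluorescence-guided
    surgery (FGS) goggle systems. Includes a pinhole-camera optical
    simulator for planar calibration targets and fluorescent well-plate
    phantoms, projective-transform (homography) estimation for dual-camera
    and camera-to-eye coalignment, frame-synchronized excitation with
    consecutive-frame NIR background subtraction, signal-to-background
    ratio (SBR) quantification against an excitation-leak threshold,
    log-log sensitivity curve fitting, parallax alignment-error audits
    across working distances for alternative head-mount geometries, and
    thermal-image-derived laser power mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    optparse,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
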