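Package: rehabsense
Title: Indoor Localization and Sparse-IMU Upper-Body Kinematics for
    In-Home Rehabilitation Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two method families for monitoring rehabilitation patients at
    home with low-cost wearables. For indoor localization from Bluetooth
    received signal strength (RSS): a log-distance-plus-shadowing channel
    simulator, neural proximity reporting to regions of interest (plain
    feed-forward and LSTM classifiers), and fingerprint k-nearest-neighbour
    positioning with a reference-point codebook. For upper-body kinematics
    from three sparse inertial measurement units (pelvis and both forearms):
    quaternion rotation algebra, pelvis-frame normalization and forward
    kinematics of a 15-segment skeleton, sensor-to-segment calibration of
    standalone IMUs onto a motion-capture convention, four sequence models
    (recurrent encoder-decoder with and without attention, transformer
    encoder, full transformer) trained with a mean-absolute-error loss on
    quaternion components, and orientation/joint-angle evaluation. A seeded
    synthetic-data module emulates both the RSS traces and the 240 Hz / 60 Hz
    motion streams so every stage is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
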