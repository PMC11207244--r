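Package: poseangle
Title: Joint-Angle Estimation and Outlier Correction for Markerless Motion Capture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Post-processing toolkit for single-person 3D human pose estimation
    output. Tracks the subject's region of interest across frames from object
    detection records, detects and repairs left/right joint switches and
    misdetections through link-length derivative screening, and estimates
    joint-angle trajectories by fitting a 26 degree-of-freedom humanoid
    forward-kinematics model to 12 measured joints per frame. Fitting minimises
    the mean per-joint position error with uDEAS, a derivative-free global
    optimiser over binary-encoded variables with bisectional and unidirectional
    search sessions, multistart restarts, and cost-sensitivity-based variable
    ordering. Includes a synthetic motion generator with controlled corruption
    modes so every stage is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
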