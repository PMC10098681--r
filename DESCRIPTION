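Package: handfusion
Title: Dual-Sensor Hand-Tracking Fusion and Telerehabilitation Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hardware-free computational core of a dual-sensor touchless
    hand-telerehabilitation pipeline. Provides a 25-landmark skeletal hand
    model with a JSON-Lines session stream format, SVD (Kabsch/Umeyama)
    rigid calibration between two orthogonally mounted tracking sensors
    with axial-bias refinement, occlusion-aware sensor fusion (per-frame
    binary switch on the palm-normal projection angle, and per-joint
    speed-based switching), per-joint kinematic analytics (speed,
    acceleration, path length, range of motion) with session comparison
    and structured report export, a file-backed document store reproducing
    a clinical server's collection scheme and role model, and a synthetic
    two-sensor simulator with noise and palm-orientation-dependent
    tracking degradation so the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
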