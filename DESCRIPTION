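Package: scopesight
Title: Simulation Toolkit for Augmented-Reality Arthroscopy Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation of an augmented-reality (AR) arthroscopy
    navigation system for the elbow. Provides SE(3) rigid-transform algebra
    and closed-form absolute orientation, a simulated stereo optical pose
    tracker with named marker templates, an oblique-viewing (angled-lens)
    arthroscope camera model with Brown-Conrady distortion and planar
    checkerboard calibration, STL organ-mesh reading/writing, a synthetic
    elbow phantom generator (bones, nerves, mounting frame), a wireframe
    overlay rendering pipeline driven by the model-to-camera transform chain,
    and a Monte-Carlo target registration error (TRE) protocol that sweeps
    the lens-cylinder rotation angle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
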