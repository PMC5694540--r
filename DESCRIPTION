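Package: hoverkin
Title: Docked Hummingbird Feeding: Strain Signals, Wingbeat Kinematics, and
    Quasi-Steady Aerodynamic Forces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for hovering hummingbirds feeding at an
    instrumented or moving feeder. Provides an instrumented-feeder strain
    signal pipeline (through-origin calibration, feed segmentation with
    conservative cropping, linear detrending, peak-to-peak amplitude ratios,
    Welch band spectral-power ratios for licking, wingbeat and mains bands,
    and mean push in body-weight units), extraction of wingbeat-kinematic
    variables from 3D landmark trajectories (zero-phase Butterworth
    filtering, stroke-plane fitting and stroke segmentation, head-aligned
    frame transform, wing bank angle, body angles, travel angle, geometric
    angle of attack, bill insertion), a quasi-steady blade-element
    aerodynamic force model with empirically derived lift/drag coefficient
    curves and Rankine-Froude induced velocity, projected visual stimulus
    geometry, and seeded synthetic-data generators that emulate the strain
    and motion-capture recordings so every stage of the pipeline is
    testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
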