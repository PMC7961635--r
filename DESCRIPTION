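Package: rtmsk
Title: Real-Time Musculoskeletal Kinematics and Dynamics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Streaming analysis of human movement with rigid-body
    musculoskeletal models. Provides marker- and IMU-based inverse
    kinematics with heading calibration and marker completion, a causal
    low-pass FIR plus smoothing-spline filter for real-time
    differentiation of generalized coordinates, recursive Newton-Euler
    inverse dynamics, prediction of ground reaction forces and moments
    from kinematics alone under the smooth transition assumption,
    static-optimization resolution of the muscle redundancy problem with
    polynomial moment-arm models, and joint reaction load analysis.
    Bundled synthetic rigid-body fixtures (pendulum, double pendulum,
    planar walker) and a deterministic gait generator make every stage
    testable without laboratory data. Reads and writes the TRC and
    MOT/STO motion-capture formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
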