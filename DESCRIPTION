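Package: ratgait
Title: Marker-Based Gait Analysis for the Rat Hindlimb
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying treadmill gait of rats from reflective-marker
    motion capture. Implements a scaled four-segment, 13-degree-of-freedom rigid-body
    model of the rat hindlimb, weighted least-squares inverse kinematics with a
    down-weighted knee marker to suppress skin artifact, TRC trajectory file I/O,
    automated heel-strike/toe-off detection on a treadmill, gait-cycle normalization
    to the 0-100% cycle, spatiotemporal parameters (cadence, stride time, swing
    percentage), ranges of motion and circular phase-shift estimation, permutation-based
    one-dimensional statistical parametric mapping of joint-angle continua, reduction
    of isometric tetanic torque sweeps to body-weight-normalized percent-of-baseline
    deficits, and a synthetic motion-capture simulator with known ground truth for
    validating every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
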