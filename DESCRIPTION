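Package: gaitreg
Title: Marker Registration and Constrained Inverse Kinematics for
    Rigid-Body Gait Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained rigid-body motion-capture toolkit for studying
    how marker registration affects joint angles and moments computed by
    constrained inverse kinematics.  Provides a kinematic-chain model with a
    canonical 12 degree-of-freedom humanoid-robot fixture, forward kinematics
    with analytic Jacobians, a weighted least-squares inverse-kinematics
    solver, anatomical reference frames built from optical markers, three
    marker-registration methods (encoder, orientation, and simulated-user
    registration), recursive Newton-Euler inverse dynamics, gait-cycle
    analysis utilities, a synthetic gait generator with dynamically
    consistent ground reactions, and readers/writers for the TRC and MOT/STO
    motion-capture formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    minpack.lm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
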