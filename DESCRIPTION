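Package: pawsim
Title: Predictive Simulation of Power-Assisted Wheelchair Propulsion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predictive simulations of manual and power-assisted wheelchair
    propulsion. A planar four-bar model of the user-wheelchair system with
    joint-level muscle torque generators and first-order activation dynamics
    is driven by an optimal controller that minimizes squared neural
    excitation. The assistance loop implements impedance control with a
    first-order mass-damper reference model tracked by a pole-cancelling PI
    velocity controller. Cyclic (steady-state) and startup maneuvers, on
    level ground and on ramps, are transcribed by Radau pseudospectral
    collocation and solved with a primal-dual interior-point method, giving
    push-phase kinematics, pushrim kinetics, joint moments, and user and
    motor effort across assistance settings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
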