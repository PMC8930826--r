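---
title: "Predictive simulation of power-assisted wheelchair propulsion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive simulation of power-assisted wheelchair propulsion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pawsim)
```

pawsim predicts how a wheelchair user propels a manual or power-assisted
wheelchair by solving optimal control problems over a musculoskeletal
model of the upper extremity coupled to the chair. This vignette is the
package's account of the science: the mechanical model and its
assumptions, the reconstructed muscle model and its calibration, the
impedance-control assistance loop, the collocation/interior-point
numerics, and the limits of what the simulations can show.

## The user–wheelchair model

The system is planar and bilaterally symmetric: upper arms, forearms
(with hands), rear wheels, and one lumped body for everything else.
Arm segment masses and inertias are bilateral totals; the wheel spin
inertia is the two-wheel total. The frame has x forward along the
direction of motion and y measured downward from the shoulder, which
sits at a fixed offset (H = 0.05 m forward is taken as the axle
position relative to the shoulder, Y = 0.75 m below the shoulder). The
wheel rolls without slip, so the forward displacement is `Rw * theta`.

Two phases alternate. In *recovery* the hands are off the pushrim and
the system has three degrees of freedom, `q = (alpha, beta, theta)`:
upper arm angle, forearm angle (both from the direction of motion,
positive downward, so a hanging arm has `alpha = beta = pi/2`), and
wheel rotation. In *propulsion* the hand grips a material point of the
rim; the grip is an ideal hinge, closing a four-bar loop whose two
closure equations leave a single degree of freedom. The hand's rim
angle, measured from the forward horizontal through the axle, coincides
with the wheel coordinate during a push; contact around -110 degrees
and release around -45 degrees sweep the top of the rim.

The recovery equations of motion `M(q) q'' + k(q, q') = ke` were
derived by hand and are verified in the test suite against an
independent computer-algebra (Lagrangian) derivation to machine
precision, and against a purely numeric energy-based oracle. The
propulsion phase is transcribed in reduced coordinates through the
chain Jacobian `J = dq/dtheta` (implicit differentiation of the
closure); the equivalent Lagrange-multiplier formulation provides the
hand-pushrim constraint force, whose tangential component gives the
user pushrim torque `tau_p` and the per-hand tangential force reported
in the summaries. Forces and moments printed by `summarize_solution()`
are per side (half the bilateral totals), the convention of
experimental pushrim studies.

External forces: gravity (rotated by the ramp angle in the chassis
frame for slope conditions), a constant-magnitude rolling resistance of
20 N opposing motion (regularized by a smooth sign function of width
1e-3 m/s so the from-rest dynamics stay differentiable; the ramp
correction `cos 3deg ~ 0.9986` is neglected), and the motor torque on
the wheel coordinate when assistance is on. Anthropometric defaults
describe a 1.70 m, 70 kg user; `anthropometry()` regenerates the
segment table from height and mass with standard fractions (the
forearm segment includes the hand, giving the 0.34 m elbow-to-grip
length).

## Joint-level muscles: reconstruction and calibration

Four muscle groups act about the shoulder and elbow: shoulder
extensors/flexors (in `alpha`) and elbow extensors/flexors (in the
elbow flexion angle `alpha - beta`, 0 at full extension). Each group
produces `tau = a * Tmax * fL(angle) * fV(rate)` with first-order
activation dynamics between neural excitation `u` and activation `a`
(time constants 20/40 ms); passive double-exponential torques engage at
the range limits (shoulder [-1, 2.4] rad, elbow [0, 2.6] rad), and a
passive viscous term (0.3 N m s/rad per joint) represents connective
tissue and antagonist-tone dissipation.

The torque surfaces of the population this model emulates (trained
wheelchair athletes) are not publicly tabulated, so the package uses
standard parametric forms and calibrates them once against published
steady-state propulsion benchmarks; the calibration is a documented,
configurable step (`muscle_params()`), not hidden constants:

* `fL` is Gaussian in the joint angle with per-group optima at the
  stretched end of each group's working range (shoulder flexors at
  `alpha = 2.25` rad, i.e. arm back; extensors 1.2; elbow extensors at
  1.3 rad flexion, flexors 0.8), width 0.5 rad. Sharper, stretched-side
  optima are what make the experimentally observed wide-arc push
  (contact near -110 degrees) the optimizer's preferred pattern; with
  flat or mid-range curves the optimum collapses to a short,
  fast-cadence push arc that is not seen in human data.
* `fV` is a Hill hyperbola (curvature 4) vanishing at 12 rad/s
  shortening, with an eccentric plateau of 1.15. The low plateau keeps
  eccentric braking of the arm swing appropriately expensive; with a
  high plateau the predicted shoulder extension moment peaks severalfold
  above measured values.
* `Tmax` (bilateral: se 120, sf 340, ee 160, ef 160 N m) is set so the
  steady-state reference simulation is clearly submaximal (peak
  shoulder-flexor activation about 0.2) while startup approaches
  maximal effort, mirroring the reported activation levels.

What the calibrated model reproduces in the unassisted level
steady-state reference: cadence, push time, push angle and contact
angle within about 10%, and the peak shoulder extension moment almost
exactly. What it does not: the recovery time runs about 25-30% long,
and the predicted push concentrates force early in the stroke, leaving
the peak tangential force and peak shoulder flexion moment high by
roughly 1.4x and 2.5x. These residuals are the footprint of the
unavailable subject-specific torque surfaces; they are reported, not
tuned away.

## The impedance-control loop

Assistance imposes a first-order mass-damper reference dynamics
`Mi vr' + Ci vr = tau_p / Rw` between user torque and chair speed. The
nominal `(Mi, Ci)` are identified by output-error least squares
(`identify_first_order()`, exact first-order-hold simulation inside a
Levenberg-Marquardt fit with a log-parameter multistart) on the
pushrim-torque/wheel-speed record of the unassisted level-ground
startup simulation - the only startup record that exists before the
controller does. A PI velocity controller designed by pole-zero
cancellation on the identified plant (`Ki/Kp = Ci/Mi`, closed-loop time
constant 0.02 s) tracks `omega_r = vr / Rw`; scenario settings scale
the reference model's `Mi` and/or `Ci` by 0.5 while the PI gains stay
designed on the nominal plant. The disturbance torque input exists in
the interface (default 0), and motor torque is unbounded, as in the
study design.

## Optimal control transcription and solution

Each scenario minimizes the physiological effort
`Wp = integral(u_se^2 + u_sf^2 + u_ee^2 + u_ef^2) dt` subject to the
phase dynamics, state continuity across phases, closure and
velocity-level closure at every propulsion entry, bounds
`u, a in [0, 1]`, joint-range boxes, an average speed of 0.9 m/s, and
(startup) rest start with 1.6 m displacement - hence a fixed total time
of 16/9 s. Steady state adds full-cycle periodicity; the re-grip at
each new contact lets the hand land on any rim material point, so only
the posture and rates are periodic. Motor effort
`Wm = integral(tau_m^2) dt` is reported, never minimized.

Transcription is flipped-Radau pseudospectral per phase segment
(collocation nodes include the segment end; differentiation matrix of
the Lagrange interpolant anchored at the segment start). Segment
boundaries within a phase follow a Legendre-Gauss-Lobatto distribution,
refining toward the phase interfaces; a uniform spacing is also
available. Phase durations are free variables (time is scaled per
phase). Recovery states carry `(alpha, alpha - beta, ...)` so the elbow
range is a plain box bound - an interior-point method then cannot step
into the hyperextension region where the passive exponential explodes.

The nonlinear programs are solved by the package's own primal-dual
interior-point method (`R/nlp_solver.R`): log barriers on the bounds
with a monotone barrier schedule, Newton steps on the primal-dual KKT
system with inertia-free regularization, fraction-to-the-boundary, and
a line-search filter. Constraint Jacobians are exact (the collocation
structure is assembled analytically; the dynamics blocks come from
complex-step differentiation, with `atan2` continued to first order);
the Lagrangian Hessian is exact up to a forward difference of the
complex-step gradient. Convergence tolerance is 1e-6 on the KKT error;
identical inputs give identical iterates.

Initial guesses are built from typical propulsion patterns: push and
recovery durations of 0.395/0.545 s for steady cycles, a contact angle
near -110 degrees, constant or ramped wheel speed, low constant
activations, and - decisive for reaching the physiological optimum - a
recovery arm trajectory obtained by forward-integrating the passive
swing (the arm flies forward-up, gravity reverses it). A pinned
presolve (durations and contact/release angles restricted to windows
around that pattern, loose tolerance) produces the warm start for the
free problem; all reported solutions are solutions of the free problem.
Assisted scenarios are warm-started from the unassisted reference by
inserting the controller states, then continue through the parameter
combinations (nominal first, then single reductions, then both);
solutions with a contact angle below -150 degrees or a push angle above
120 degrees are treated as clearly unrealistic local minima and re-run
from the alternative neighbouring seed, and solver failures fall back
through the remaining seeds.

## Problem sizes and numerical choices

The default meshes are 3 segments of order 4 per steady-state phase and
2x3 (propulsion) / 3x4 (recovery) for startup phases - a few hundred
decision variables per problem, solving in tens of seconds to a couple
of minutes. The mesh density of the reported study (5x20 steady;
10x10/12x12 startup) is available as the `"fine"` profile; the
acceptance checks verify that doubling the polynomial order changes the
steady-state effort by less than 1%. Re-integrating a converged
solution's controls with an adaptive-step integrator reproduces the
propulsion-phase states to about 2e-3 at the default mesh and better
than 1e-3 with the order doubled; the recovery phase converges only
algebraically under refinement (a fast elbow mode plus excitations
switching on and off their bounds inside segments) and still shows
about 1e-2 deviations at a 12x6 mesh — the study-density recovery
meshes exist for exactly this reason. The test suite uses a
further-coarsened mesh for the qualitative ordering properties.
Solver tolerances (1e-6), the rolling-resistance regularization width
(1e-3 m/s), the closure branch (anatomically natural, elbow posterior,
held fixed), and the bound boxes are fixed and logged; startup
activations at t = 0 are free (the chair, the reference model and the
PI integrator start at rest/zero).

## What the synthetic fixtures do and do not emulate

The generators (`anthropometry`, `synthetic_first_order`,
`forward_simulate`, `initial_guess`) produce every input the pipeline
needs without external data: anthropometric parameter sets, noisy
first-order records for the identification tests (exact discrete
simulation plus seeded Gaussian noise), independent forward
simulations, and kinematically consistent optimizer guesses. They
emulate the *modelled* system - they share its idealizations (planar,
bilateral, fixed shoulder, ideal grip, constant rolling resistance), so
passing tests demonstrate internal consistency and correct numerics,
not fidelity to any individual user: trunk motion, 3-D shoulder
kinematics, grip force limits, tire slip and air drag are all outside
the model.

## Known limitations

* The muscle torque surfaces are reconstructions; effort magnitudes
  (`Wp`, `Wm`) are therefore loose, and the assistance findings are
  read at the level of orderings and signs, which are robust across
  the calibration sweeps.
* The predicted startup front-loads the pushes and ends with a short
  final push, which lowers the speed of the coasting segments of the
  identification record; the identified apparent damping accordingly
  runs above, and the apparent mass below, the published values.
* The interior-point solver is compact and deterministic but not
  globalized: distinct initial-guess basins exist (fast short-arc
  cycles), which is why the guess policy and the unrealistic-pattern
  detector are part of the documented method, exactly as in predictive
  simulation practice.
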