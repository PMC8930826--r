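# Joint-level muscle torque generators.
#
# Four equivalent muscle groups - shoulder extensors (se), shoulder
# flexors (sf), elbow extensors (ee), elbow flexors (ef) - produce
# active torques a * Tmax * fL(angle) * fV(rate) about their joint, plus
# passive joint torques engaging exponentially toward the range limits.
# Joint angle conventions: shoulder angle is the upper arm angle alpha;
# elbow flexion angle is e = alpha - beta (0 = full extension). Shoulder
# flexion acts in the direction of decreasing alpha (arm swinging
# forward/up), elbow flexion in the direction of increasing e.
#
# The torque surfaces are standard, smooth parameterizations (Gaussian
# torque-angle curve, Hill-type torque-angular-velocity curve with an
# eccentric plateau, double-exponential passive torque): everything is
# C1, as required by gradient-based trajectory optimization. Maximal
# isometric torques are a documented calibration: defaults are set so
# that unassisted reference simulations are submaximal, with peak
# shoulder-flexor activation near 0.14 in steady-state and near 0.55 in
# startup maneuvers.

#' Muscle group parameter sets
#'
#' @param Tmax Named vector of maximal isometric torques (N m,
#'   bilateral) for the groups `se`, `sf`, `ee`, `ef`.
#' @param fl_center Named vector (rad): torque-angle optimum per group,
#'   in the joint angle of the group (`alpha` for shoulder groups,
#'   `alpha - beta` for elbow groups). Defaults place each optimum at
#'   the stretched end of the group's working range (flexors strongest
#'   with the joint extended and vice versa), the usual shape of
#'   torque-angle curves.
#' @param fl_width Torque-angle Gaussian width (rad).
#' @param vmax Maximal shortening rate (rad/s) at which active torque
#'   vanishes.
#' @param fv_curvature Hill curvature of the concentric branch.
#' @param fv_ecc Eccentric plateau (multiple of isometric torque).
#' @param shoulder_limits,elbow_limits Joint range limits (rad) where
#'   passive torques engage; also used as coordinate bounds in the
#'   optimal control problems.
#' @param passive_scale Passive torque scale (N m).
#' @param passive_decay Exponential engagement length (rad).
#' @param passive_damping Passive joint viscous damping coefficient
#'   (N m s/rad, bilateral), applied about each joint in opposition to
#'   the joint rate; represents the velocity-dependent dissipation of
#'   connective tissue and antagonist tone.
#' @param Ta,Td Activation and deactivation time constants (s).
#' @return A `paw_muscles` list.
#' @export
muscle_params <- function(Tmax = c(se = 120, sf = 340, ee = 160, ef = 160),
                          fl_center = c(se = 1.2, sf = 2.25,
                                        ee = 1.3, ef = 0.8),
                          fl_width = 0.5,
                          vmax = 12,
                          fv_curvature = 4,
                          fv_ecc = 1.15,
                          shoulder_limits = c(-1.0, 2.4),
                          elbow_limits = c(0.0, 2.6),
                          passive_scale = 2.0,
                          passive_decay = 0.05,
                          passive_damping = 0.3,
                          Ta = 0.020, Td = 0.040) {
  stopifnot(all(Tmax > 0), all(c("se", "sf", "ee", "ef") %in% names(Tmax)),
            all(fl_width > 0), vmax > 0, fv_ecc >= 1, Ta > 0, Td > 0,
            Ta < Td)
  structure(list(Tmax = Tmax[c("se", "sf", "ee", "ef")],
                 fl_center = fl_center, fl_width = fl_width,
                 vmax = vmax, fv_curvature = fv_curvature, fv_ecc = fv_ecc,
                 shoulder_limits = shoulder_limits,
                 elbow_limits = elbow_limits,
                 passive_scale = passive_scale,
                 passive_decay = passive_decay,
                 passive_damping = passive_damping,
                 Ta = Ta, Td = Td),
            class = "paw_muscles")
}

#' Default muscle group parameters
#' @return A `paw_muscles` list, see [muscle_params()].
#' @export
default_muscles <- function() muscle_params()

#' Read / write muscle parameters (YAML)
#'
#' One block per field; round-trip lossless.
#' @param m A `paw_muscles` object.
#' @param path YAML file path.
#' @export
write_muscles <- function(m, path) {
  stopifnot(inherits(m, "paw_muscles"))
  yaml::write_yaml(lapply(unclass(m), function(x) as.list(x)), path,
                   precision = 15)
  invisible(path)
}

#' @rdname write_muscles
#' @export
read_muscles <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(muscle_params, lapply(v, function(x) unlist(x)))
}

#' Activation dynamics rate
#'
#' First-order excitation-activation lag
#' `da/dt = (u - a) (u/Ta + (1 - u)/Td)`: the effective rate constant
#' blends the activation time constant when excitation is high and the
#' deactivation time constant when it is low. The form keeps `a` inside
#' `[0, 1]` for any measurable `u(t)` in `[0, 1]`.
#'
#' @param a Activation in `[0, 1]`.
#' @param u Neural excitation in `[0, 1]`.
#' @param Ta Activation time constant (s).
#' @param Td Deactivation time constant (s).
#' @return `da/dt` (1/s).
#' @export
activation_rate <- function(a, u, Ta = 0.020, Td = 0.040) {
  if (any(re_(a) < -1e-9) || any(re_(a) > 1 + 1e-9) ||
      any(re_(u) < -1e-9) || any(re_(u) > 1 + 1e-9)) {
    stop("activation and excitation must lie in [0, 1]", call. = FALSE)
  }
  (u - a) * (u / Ta + (1 - u) / Td)
}

# torque-angular-velocity scaling; w = shortening rate (rad/s), positive
# when the muscle group shortens. Hill-type concentric branch, value 1
# and slope matched at w = 0 to an exponential eccentric branch that
# saturates at the plateau fv_ecc; C1 everywhere, exact at w = 0. The
# concentric rational is used unclipped past vmax (mildly negative,
# bounded below by -1/K), which keeps the surface smooth for the
# optimizer; rates beyond vmax do not occur in converged solutions.
fv_scale <- function(w, m) {
  wbar <- w / m$vmax
  K <- m$fv_curvature
  N <- m$fv_ecc
  cc <- (1 + K) / (N - 1)
  neg <- Re(wbar) < 0
  out <- wbar
  out[neg] <- N - (N - 1) * exp(cc * wbar[neg])
  out[!neg] <- (1 - wbar[!neg]) / (1 + K * wbar[!neg])
  out
}

# torque-angle scaling (Gaussian), per muscle group; width may be a
# scalar or a named per-group vector
fl_scale <- function(angle, m, group) {
  w <- if (length(m$fl_width) > 1L) m$fl_width[[group]] else m$fl_width
  exp(-((angle - m$fl_center[[group]]) / w)^2)
}

#' Active torque of one muscle group
#'
#' `tau = a * Tmax * fL(angle) * fV(rate)`, where `rate` is the joint
#' rate and the shortening rate of the group is derived from its action
#' sign. Returned torque is signed about the group's joint coordinate
#' (shoulder: positive = extension, increasing `alpha`; elbow: positive
#' = flexion, increasing `alpha - beta`).
#'
#' @param group One of `"se"`, `"sf"`, `"ee"`, `"ef"`.
#' @param a Activation in `[0, 1]`.
#' @param joint_angle Joint angle (rad): `alpha` for shoulder groups,
#'   `alpha - beta` for elbow groups.
#' @param joint_rate Joint angular rate (rad/s), same convention.
#' @param muscles A `paw_muscles` object.
#' @return Signed torque (N m, bilateral).
#' @export
active_torque <- function(group, a, joint_angle, joint_rate,
                          muscles = default_muscles()) {
  group <- match.arg(group, c("se", "sf", "ee", "ef"))
  # action direction about the joint coordinate
  dir <- switch(group, se = +1, sf = -1, ee = -1, ef = +1)
  shortening <- dir * joint_rate
  mag <- a * muscles$Tmax[[group]] * fl_scale(joint_angle, muscles, group) *
    fv_scale(shortening, muscles)
  dir * mag
}

#' Passive joint torque
#'
#' Double-exponential ligament/connective-tissue torque: essentially
#' zero in mid-range, engaging exponentially toward the joint limits and
#' opposing further excursion.
#'
#' @param joint `"shoulder"` or `"elbow"`.
#' @param joint_angle Joint angle (rad), conventions as in
#'   [active_torque()].
#' @param muscles A `paw_muscles` object.
#' @return Torque (N m, bilateral), signed about the joint coordinate.
#' @export
passive_torque <- function(joint, joint_angle,
                           muscles = default_muscles()) {
  joint <- match.arg(joint, c("shoulder", "elbow"))
  lim <- if (joint == "shoulder") muscles$shoulder_limits else muscles$elbow_limits
  k <- muscles$passive_scale; d <- muscles$passive_decay
  k * (exp(-(joint_angle - lim[1]) / d) - exp((joint_angle - lim[2]) / d))
}

# net joint torques from an activation vector a = (se, sf, ee, ef);
# complex safe; returns c(tau_shoulder_about_alpha, tau_elbow_flexion)
net_torques_core <- function(a, alpha, beta, ad, bd, m) {
  e <- alpha - beta
  ed <- ad - bd
  tau_s <- a[1] * m$Tmax[["se"]] * fl_scale(alpha, m, "se") *
    fv_scale(ad, m) -
    a[2] * m$Tmax[["sf"]] * fl_scale(alpha, m, "sf") * fv_scale(-ad, m) +
    passive_torque_core(alpha, m$shoulder_limits, m) -
    m$passive_damping * ad
  tau_e <- a[4] * m$Tmax[["ef"]] * fl_scale(e, m, "ef") *
    fv_scale(ed, m) -
    a[3] * m$Tmax[["ee"]] * fl_scale(e, m, "ee") * fv_scale(-ed, m) +
    passive_torque_core(e, m$elbow_limits, m) -
    m$passive_damping * ed
  c(tau_s, tau_e)
}

passive_torque_core <- function(angle, lim, m) {
  m$passive_scale * (exp(-(angle - lim[1]) / m$passive_decay) -
                       exp((angle - lim[2]) / m$passive_decay))
}

#' Net joint torques from the activation state
#'
#' Sums agonist, antagonist and passive contributions per joint. The
#' shoulder torque is reported about the upper arm angle `alpha`
#' (positive = extension direction); the elbow torque about the elbow
#' flexion angle `alpha - beta` (positive = flexion).
#'
#' @param activations Named or ordered vector `(se, sf, ee, ef)` in
#'   `[0, 1]`.
#' @inheritParams constraint_residual
#' @param muscles A `paw_muscles` object.
#' @return Length-2 vector `(tau_shoulder, tau_elbow)` (N m, bilateral).
#' @export
net_joint_torques <- function(activations, state,
                              muscles = default_muscles()) {
  if (!is.null(names(activations))) {
    activations <- activations[c("se", "sf", "ee", "ef")]
  }
  net_torques_core(activations, state$alpha, state$beta,
                   state$alpha_dot, state$beta_dot, muscles)
}
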