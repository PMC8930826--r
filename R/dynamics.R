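# Rigid-body dynamics of the user-wheelchair system.
#
# Recovery phase: three degrees of freedom q = (alpha, beta, theta) with
# equations of motion M(q) qdd + k(q, qd) = ke(q, qd). Propulsion phase:
# the hand-pushrim closure reduces the system to the single wheel
# coordinate, either through the chain Jacobian (minimal form) or through
# the augmented multiplier system, which also yields the hand-pushrim
# constraint force.
#
# Gravity on a ramp is handled by rotating the gravity vector by the ramp
# angle in the chassis frame; rolling resistance is a constant-magnitude
# force opposing motion, regularized by a smooth sign function of width
# `speed_eps` (m/s) so that the from-rest dynamics stay differentiable.

.paw_speed_eps <- 1e-3

# mass matrix and generalized Coriolis/centrifugal vector; complex safe
dyn_terms <- function(alpha, beta, alpha_dot, beta_dot, p) {
  A <- p$upper_arm_length; ra <- p$upper_arm_com
  rb <- p$forearm_com; Rw <- p$wheel_radius
  ma <- p$upper_arm_mass; mb <- p$forearm_mass
  Ia <- p$upper_arm_inertia; Ib <- p$forearm_inertia
  cab <- cos(alpha - beta); sab <- sin(alpha - beta)
  sa <- sin(alpha); sb <- sin(beta)
  m11 <- ma * ra^2 + Ia + mb * A^2
  m22 <- mb * rb^2 + Ib
  m12 <- mb * A * rb * cab
  m13 <- -(ma * ra + mb * A) * sa * Rw
  m23 <- -mb * rb * sb * Rw
  m33 <- p$combined_mass * Rw^2 + p$wheel_inertia
  M <- matrix(c(m11, m12, m13,
                m12, m22, m23,
                m13, m23, m33), 3, 3)
  k <- c(mb * A * rb * sab * beta_dot^2,
         -mb * A * rb * sab * alpha_dot^2,
         -Rw * ((ma * ra + mb * A) * cos(alpha) * alpha_dot^2 +
                  mb * rb * cos(beta) * beta_dot^2))
  list(M = M, k = k)
}

#' Dynamics terms of the current phase
#'
#' Mass matrix, Coriolis vector and (for propulsion) the chain Jacobian
#' of the reduced one-degree-of-freedom dynamics.
#'
#' @inheritParams constraint_residual
#' @return For recovery, a list with `M` (3x3, symmetric positive
#'   definite) and `k` (length 3). For propulsion additionally `J`,
#'   `dJdt` and the scalar `reduced_inertia` = t(J) M J.
#' @export
dynamics_terms <- function(state, params) {
  dt_ <- dyn_terms(state$alpha, state$beta, state$alpha_dot,
                   state$beta_dot, params)
  if (identical(state$phase, "propulsion")) {
    jj <- chain_jacobian(state, params)
    dt_$J <- jj$J
    dt_$dJdt <- jj$dJdt
    dt_$reduced_inertia <- drop(crossprod(jj$J, dt_$M %*% jj$J))
  }
  dt_
}

# generalized applied forces; complex safe.
# tau_s: net shoulder torque about alpha (positive = extension direction,
#        increasing alpha); tau_e: net elbow torque about the elbow
#        flexion angle e = alpha - beta (positive = flexion).
applied_forces_core <- function(alpha, beta, theta_dot, tau_s, tau_e,
                                tau_m, p, speed_eps = .paw_speed_eps) {
  g <- p$gravity; eta <- p$ramp_angle; Rw <- p$wheel_radius
  ga <- (p$upper_arm_mass * p$upper_arm_com +
           p$forearm_mass * p$upper_arm_length) * g * cos(alpha - eta)
  gb <- p$forearm_mass * p$forearm_com * g * cos(beta - eta)
  v <- theta_dot * Rw
  roll <- -p$rolling_resistance * tanh(v / speed_eps) * Rw
  slope <- -p$combined_mass * g * sin(eta) * Rw
  c(ga + tau_s + tau_e,
    gb - tau_e,
    roll + slope + tau_m)
}

#' Generalized applied force vector
#'
#' Collects the bilateral joint torques, gravity (rotated by the ramp
#' angle), rolling resistance opposing motion, and the motor torque on
#' the wheel coordinate.
#'
#' @inheritParams constraint_residual
#' @param joint_torques Length-2 vector `(tau_shoulder, tau_elbow)` in
#'   N m: shoulder torque about the upper arm angle (positive in the
#'   direction of increasing `alpha`, i.e. extension), elbow torque about
#'   the elbow flexion angle `alpha - beta` (positive flexion).
#' @param motor_torque Motor torque on the rear wheels (N m, bilateral).
#' @param params A `paw_params` object.
#' @return Length-3 generalized force vector `ke`.
#' @export
applied_forces <- function(state, joint_torques = c(0, 0), motor_torque = 0,
                           params) {
  applied_forces_core(state$alpha, state$beta, state$theta_dot,
                      joint_torques[1], joint_torques[2], motor_torque,
                      params)
}

#' Recovery-phase accelerations
#'
#' Solves the three-degree-of-freedom equations of motion for the
#' generalized accelerations.
#'
#' @inheritParams applied_forces
#' @param ke Generalized force vector (length 3), e.g. from
#'   [applied_forces()].
#' @return Length-3 acceleration vector `(alpha_dd, beta_dd, theta_dd)`.
#' @export
recovery_accel <- function(state, ke, params) {
  dt_ <- dyn_terms(state$alpha, state$beta, state$alpha_dot,
                   state$beta_dot, params)
  if (!is.complex(dt_$M)) {
    ev <- eigen(dt_$M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      stop("mass matrix not positive definite: inconsistent model ",
           "parameters", call. = FALSE)
    }
  }
  drop(solve(dt_$M, ke - dt_$k))
}

#' Propulsion-phase acceleration (minimal form)
#'
#' Reduced single-degree-of-freedom dynamics of the closed chain,
#' obtained by projecting the full equations of motion onto the chain
#' Jacobian.
#'
#' @inheritParams recovery_accel
#' @return Scalar wheel acceleration `theta_dd` (rad/s^2).
#' @export
propulsion_accel <- function(state, ke, params) {
  dt_ <- dyn_terms(state$alpha, state$beta, state$alpha_dot,
                   state$beta_dot, params)
  jj <- chain_jacobian(state, params)
  J <- jj$J
  m_red <- drop(crossprod(J, dt_$M %*% J))
  rhs <- drop(crossprod(J, ke - dt_$k - dt_$M %*% (jj$dJdt * state$theta_dot)))
  rhs / m_red
}

# full constraint Jacobian d c / d q (2 x 3) and the velocity-product
# term (dC/dt) qd; complex safe
closure_jacobian_full <- function(alpha, beta, theta, ad, bd, td, p) {
  A <- p$upper_arm_length; B <- p$forearm_length; Rp <- p$pushrim_radius
  C <- matrix(c(-A * sin(alpha), A * cos(alpha),
                -B * sin(beta),  B * cos(beta),
                Rp * sin(theta), -Rp * cos(theta)), 2, 3)
  Cdot_qd <- c(-A * cos(alpha) * ad^2 - B * cos(beta) * bd^2 +
                 Rp * cos(theta) * td^2,
               -A * sin(alpha) * ad^2 - B * sin(beta) * bd^2 +
                 Rp * sin(theta) * td^2)
  list(C = C, Cdot_qd = Cdot_qd)
}

# augmented (Lagrange multiplier) propulsion dynamics: returns full qdd
# and the constraint force lambda (N, bilateral hand force components in
# the x-forward / y-down frame as applied to the hand). Complex safe.
propulsion_multiplier_core <- function(alpha, beta, theta, ad, bd, td,
                                       ke, p) {
  dt_ <- dyn_terms(alpha, beta, ad, bd, p)
  cj <- closure_jacobian_full(alpha, beta, theta, ad, bd, td, p)
  A5 <- rbind(cbind(dt_$M, -t(cj$C)),
              cbind(cj$C, matrix(0, 2, 2)))
  rhs <- c(ke - dt_$k, -cj$Cdot_qd)
  sol <- solve(A5, rhs)
  list(qdd = sol[1:3], lambda = sol[4:5])
}

#' Hand-pushrim reaction force and user torque
#'
#' Recovers the hand-pushrim contact force as the constraint force of the
#' closure equations (Lagrange multiplier formulation). `Ft` is the
#' per-hand component tangential to the pushrim at the hand; `tau_p` is
#' the bilateral user pushrim torque `2 Ft Rp`. Both are exactly zero in
#' the recovery phase (no contact).
#'
#' @inheritParams applied_forces
#' @return List with `force` (bilateral hand force components, N),
#'   `Ft` (per-hand tangential force, N), and `tau_p` (bilateral user
#'   pushrim torque, N m), plus the full accelerations `qdd`.
#' @export
hand_reaction <- function(state, joint_torques = c(0, 0), motor_torque = 0,
                          params) {
  if (identical(state$phase, "recovery")) {
    return(list(force = c(0, 0), Ft = 0, tau_p = 0, qdd = NULL))
  }
  ke <- applied_forces(state, joint_torques, motor_torque, params)
  sol <- propulsion_multiplier_core(state$alpha, state$beta, state$theta,
                                    state$alpha_dot, state$beta_dot,
                                    state$theta_dot, ke, params)
  lam <- sol$lambda
  # force applied by the hand on the rim is -lambda; its tangential
  # component times Rp is the generalized constraint force on theta
  tau_p <- params$pushrim_radius *
    (lam[1] * sin(state$theta) - lam[2] * cos(state$theta))
  list(force = lam, Ft = tau_p / (2 * params$pushrim_radius),
       tau_p = tau_p, qdd = sol$qdd)
}

# --- energy bookkeeping (audit oracle for integrators and tests) -------

kinetic_energy <- function(state, p) {
  dt_ <- dyn_terms(state$alpha, state$beta, state$alpha_dot,
                   state$beta_dot, p)
  qd <- c(state$alpha_dot, state$beta_dot, state$theta_dot)
  0.5 * drop(crossprod(qd, dt_$M %*% qd))
}

# potential energy with x = Rw * theta (y measured downward)
potential_energy <- function(state, p) {
  g <- p$gravity; eta <- p$ramp_angle
  x <- p$wheel_radius * state$theta
  ya <- p$upper_arm_com * sin(state$alpha)
  xa <- p$upper_arm_com * cos(state$alpha)
  yb <- p$upper_arm_length * sin(state$alpha) +
    p$forearm_com * sin(state$beta)
  xb <- p$upper_arm_length * cos(state$alpha) +
    p$forearm_com * cos(state$beta)
  g * sin(eta) * (p$combined_mass * x +
                    p$upper_arm_mass * xa + p$forearm_mass * xb) -
    g * cos(eta) * (p$upper_arm_mass * ya + p$forearm_mass * yb)
}

total_energy <- function(state, p) {
  kinetic_energy(state, p) + potential_energy(state, p)
}
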