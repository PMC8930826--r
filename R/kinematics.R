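# Planar kinematics of the user-wheelchair four-bar.
#
# Frame convention: origin at the shoulder, x forward along the direction
# of motion, y positive downward. The wheel axle sits at (H, Y). The hand
# angle on the pushrim equals the wheel coordinate theta, measured from
# the forward horizontal through the axle; with this convention forward
# rolling has positive theta-rate and the hand sweeps the upper part of
# the rim from contact (about -110 deg) to release (about -45 deg).
#
# All low-level kinematics accept complex scalars so that derivatives can
# be obtained by complex-step differentiation; atan2 is continued to
# first order via cs_atan2.

re_ <- function(x) if (is.complex(x)) Re(x) else x

# first-order analytic continuation of atan2 for complex-step use
cs_atan2 <- function(y, x) {
  if (is.complex(y) || is.complex(x)) {
    yr <- Re(y); xr <- Re(x)
    complex(real = atan2(yr, xr),
            imaginary = (xr * Im(y) - yr * Im(x)) / (xr^2 + yr^2))
  } else {
    atan2(y, x)
  }
}

# hand target point on the pushrim, relative to the shoulder
rim_target <- function(theta, p) {
  c(p$shoulder_offset_h + p$pushrim_radius * cos(theta),
    p$shoulder_offset_v + p$pushrim_radius * sin(theta))
}

#' System state of the user-wheelchair model
#'
#' @param alpha Upper arm angle (rad), measured from the direction of
#'   motion, positive downward; the arm hangs at `pi/2`.
#' @param beta Forearm angle (rad), same convention.
#' @param theta Rear wheel angular displacement (rad); during propulsion
#'   it equals the hand angle on the pushrim measured from the forward
#'   horizontal through the axle.
#' @param alpha_dot,beta_dot,theta_dot Angular rates (rad/s).
#' @param phase `"propulsion"` (hands on the rim, one degree of freedom)
#'   or `"recovery"` (open chain, three degrees of freedom).
#' @return A `paw_state` list.
#' @export
system_state <- function(alpha, beta, theta,
                         alpha_dot = 0, beta_dot = 0, theta_dot = 0,
                         phase = c("recovery", "propulsion")) {
  phase <- match.arg(phase)
  structure(list(alpha = alpha, beta = beta, theta = theta,
                 alpha_dot = alpha_dot, beta_dot = beta_dot,
                 theta_dot = theta_dot, phase = phase),
            class = "paw_state")
}

#' Holonomic closure residual of the hand-pushrim contact
#'
#' Residual of the loop-closure equations linking the arm angles to the
#' hand point on the pushrim. Zero iff the hand coincides with its grip
#' point on the rim.
#'
#' @param state A `paw_state` (or a list with `alpha`, `beta`, `theta`).
#' @param params A `paw_params` object.
#' @return Length-2 numeric vector (m).
#' @export
constraint_residual <- function(state, params) {
  closure_residual_abt(state$alpha, state$beta, state$theta, params)
}

closure_residual_abt <- function(alpha, beta, theta, p) {
  t <- rim_target(theta, p)
  c(p$upper_arm_length * cos(alpha) + p$forearm_length * cos(beta) - t[1],
    p$upper_arm_length * sin(alpha) + p$forearm_length * sin(beta) - t[2])
}

#' Inverse kinematics of the four-bar closure
#'
#' Solves the loop-closure equations for the arm angles given the hand
#' angle on the pushrim. The anatomically natural branch is returned
#' (elbow posterior to the shoulder-hand line, `alpha >= beta`, elbow
#' flexion angle `alpha - beta >= 0`); the branch is held fixed along
#' trajectories.
#'
#' @param theta Hand angle on the pushrim (rad).
#' @param params A `paw_params` object.
#' @return List with elements `alpha` and `beta` (rad).
#' @export
closure_solve <- function(theta, params) {
  ab <- closure_ab(theta, params)
  list(alpha = ab[1], beta = ab[2])
}

closure_ab <- function(theta, p) {
  A <- p$upper_arm_length; B <- p$forearm_length
  t <- rim_target(theta, p)
  d2 <- t[1]^2 + t[2]^2
  d2r <- re_(d2)
  if (d2r >= (A + B)^2 || d2r <= (A - B)^2) {
    stop("infeasible configuration: pushrim point at theta = ",
         signif(re_(theta), 6),
         " rad is out of reach of the closed arm chain", call. = FALSE)
  }
  d <- sqrt(d2)
  phi_t <- cs_atan2(t[2], t[1])
  # interior angle at the shoulder; natural branch alpha = phi_t + psi
  cpsi <- (A^2 + d2 - B^2) / (2 * A * d)
  psi <- acos(cpsi)
  alpha <- phi_t + psi
  ex <- t[1] - A * cos(alpha)
  ey <- t[2] - A * sin(alpha)
  beta <- cs_atan2(ey, ex)
  c(alpha, beta)
}

# Jacobian of the arm angles w.r.t. theta on the closure manifold, by
# implicit differentiation of the closure equations, plus its
# theta-derivative (needed for dJ/dt). Complex-step safe.
#
# Returns list(J = c(dalpha, dbeta, 1), dJ = c(d2alpha, d2beta, 0)).
chain_jacobian_abt <- function(alpha, beta, theta, p) {
  A <- p$upper_arm_length; B <- p$forearm_length; Rp <- p$pushrim_radius
  sa <- sin(alpha); ca <- cos(alpha)
  sb <- sin(beta);  cb <- cos(beta)
  st <- sin(theta); ct <- cos(theta)
  # d c / d(alpha, beta) and d c / d theta
  Carm <- matrix(c(-A * sa, A * ca, -B * sb, B * cb), 2, 2)
  det <- Carm[1, 1] * Carm[2, 2] - Carm[1, 2] * Carm[2, 1]  # A B sin(beta - alpha)
  if (abs(re_(det)) < 1e-10) {
    stop("singular configuration: elbow at full extension, chain Jacobian ",
         "undefined", call. = FALSE)
  }
  ctheta <- c(Rp * st, -Rp * ct)
  Jab <- solve_2x2(Carm, -ctheta, det)
  # differentiate Carm along theta (alpha, beta vary with theta through Jab)
  dCarm <- matrix(c(-A * ca * Jab[1], -A * sa * Jab[1],
                    -B * cb * Jab[2], -B * sb * Jab[2]), 2, 2)
  dctheta <- c(Rp * ct, Rp * st)
  dJab <- solve_2x2(Carm, -dctheta - dCarm %*% Jab, det)
  list(J = c(Jab[1], Jab[2], 1), dJ = c(dJab[1], dJab[2], 0))
}

solve_2x2 <- function(M, b, det) {
  c(M[2, 2] * b[1] - M[1, 2] * b[2], M[1, 1] * b[2] - M[2, 1] * b[1]) / det
}

#' Chain Jacobian of the propulsion-phase reduction
#'
#' The propulsion phase has one degree of freedom; the full coordinate
#' rates follow from the wheel rate through the chain Jacobian
#' `J = d(alpha, beta, theta)/d theta` obtained by implicit
#' differentiation of the closure equations. `dJdt` is its time
#' derivative, consistent with the current wheel rate.
#'
#' @param state A `paw_state` satisfying closure.
#' @param params A `paw_params` object.
#' @return List with `J` (length 3, third component exactly 1) and
#'   `dJdt` (length 3).
#' @export
chain_jacobian <- function(state, params) {
  jj <- chain_jacobian_abt(state$alpha, state$beta, state$theta, params)
  list(J = jj$J, dJdt = jj$dJ * state$theta_dot)
}

# feasible hand angles on the rim (where the closed chain can reach),
# midpoints well inside; used for bounds and random admissible states
rim_feasible_range <- function(p, margin = 0.02) {
  f <- function(th) {
    t <- rim_target(th, p)
    sqrt(t[1]^2 + t[2]^2)
  }
  hi <- p$upper_arm_length + p$forearm_length
  # d(theta) is unimodal on (-pi, 0); find the reachable window by bisection
  lo_edge <- stats::uniroot(function(th) f(th) - hi, c(-pi, -pi / 2))$root
  hi_edge <- stats::uniroot(function(th) f(th) - hi, c(-pi / 2, 0))$root
  c(lo_edge + margin * (hi_edge - lo_edge), hi_edge - margin * (hi_edge - lo_edge))
}
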