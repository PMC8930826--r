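# Independent oracles used across the suite.
#
# The rigid-body oracle derives the recovery-phase dynamics numerically
# from energies only: segment positions are written down independently,
# body velocities follow by differencing the position maps, the mass
# matrix from the quadratic form of the kinetic energy, the
# Coriolis/centrifugal terms from Christoffel symbols (finite
# differences of the mass matrix), and gravity from finite differences
# of the potential. Nothing is shared with the package's closed-form
# implementation except the model parameters.

oracle_positions <- function(q, p) {
  al <- q[1]; be <- q[2]; th <- q[3]
  x <- p$wheel_radius * th
  list(
    chassis = c(x, 0),
    arm = c(x + p$upper_arm_com * cos(al), p$upper_arm_com * sin(al)),
    forearm = c(x + p$upper_arm_length * cos(al) + p$forearm_com * cos(be),
                p$upper_arm_length * sin(al) + p$forearm_com * sin(be)))
}

oracle_kinetic <- function(q, qd, p, h = 1e-6) {
  pos1 <- oracle_positions(q + h * qd, p)
  pos0 <- oracle_positions(q - h * qd, p)
  v <- lapply(names(pos1), function(nm) (pos1[[nm]] - pos0[[nm]]) / (2 * h))
  names(v) <- names(pos1)
  mc <- p$combined_mass - p$upper_arm_mass - p$forearm_mass
  0.5 * (mc * sum(v$chassis^2) +
           p$upper_arm_mass * sum(v$arm^2) +
           p$forearm_mass * sum(v$forearm^2) +
           p$upper_arm_inertia * qd[1]^2 +
           p$forearm_inertia * qd[2]^2 +
           p$wheel_inertia * qd[3]^2)
}

oracle_potential <- function(q, p) {
  pos <- oracle_positions(q, p)
  g <- p$gravity; eta <- p$ramp_angle
  mc <- p$combined_mass - p$upper_arm_mass - p$forearm_mass
  m <- c(mc, p$upper_arm_mass, p$forearm_mass)
  xs <- c(pos$chassis[1], pos$arm[1], pos$forearm[1])
  ys <- c(pos$chassis[2], pos$arm[2], pos$forearm[2])  # y positive down
  sum(m * g * (sin(eta) * xs - cos(eta) * ys))
}

oracle_mass_matrix <- function(q, p) {
  M <- matrix(0, 3, 3)
  ee <- diag(3)
  for (i in 1:3) {
    for (j in i:3) {
      if (i == j) {
        M[i, i] <- 2 * oracle_kinetic(q, ee[i, ], p)
      } else {
        M[i, j] <- M[j, i] <-
          oracle_kinetic(q, ee[i, ] + ee[j, ], p) -
          oracle_kinetic(q, ee[i, ], p) - oracle_kinetic(q, ee[j, ], p)
      }
    }
  }
  M
}

# recovery-phase accelerations from the Euler-Lagrange equations with
# all derivatives taken numerically; Q_applied excludes gravity (it is
# derived from the potential here)
oracle_recovery_accel <- function(q, qd, Q_applied, p, h = 1e-5,
                                  h_chris = 1e-4) {
  M <- oracle_mass_matrix(q, p)
  # Christoffel form: k_i = sum_jk (dM_ij/dq_k - 0.5 dM_jk/dq_i) qd_j qd_k
  # (wider step: the mass-matrix values themselves carry ~1e-12
  # finite-difference noise)
  dM <- array(0, c(3, 3, 3))
  for (k in 1:3) {
    qp <- q; qp[k] <- qp[k] + h_chris
    qm <- q; qm[k] <- qm[k] - h_chris
    dM[, , k] <- (oracle_mass_matrix(qp, p) -
                    oracle_mass_matrix(qm, p)) / (2 * h_chris)
  }
  kvec <- numeric(3)
  for (i in 1:3) {
    s <- 0
    for (j in 1:3) for (k in 1:3) {
      s <- s + (dM[i, j, k] - 0.5 * dM[j, k, i]) * qd[j] * qd[k]
    }
    kvec[i] <- s
  }
  Qg <- numeric(3)
  for (i in 1:3) {
    qp <- q; qp[i] <- qp[i] + h
    qm <- q; qm[i] <- qm[i] - h
    Qg[i] <- -(oracle_potential(qp, p) - oracle_potential(qm, p)) / (2 * h)
  }
  solve(M, Q_applied + Qg - kvec)
}

# propulsion-phase acceleration by the Lagrange-multiplier formulation,
# assembled independently with numerically differentiated constraint
# terms
oracle_propulsion_multiplier <- function(q, qd, Q_total, p, h = 1e-6) {
  cfun <- function(qq) constraint_residual(
    list(alpha = qq[1], beta = qq[2], theta = qq[3]), p)
  # constraint Jacobian by complex step (exact), at shifted positions
  cjac <- function(qq) {
    C <- matrix(0, 2, 3)
    hc <- 1e-20
    for (j in 1:3) {
      qc <- as.complex(qq); qc[j] <- qc[j] + hc * 1i
      C[, j] <- Im(cfun(qc)) / hc
    }
    C
  }
  C <- cjac(q)
  # (dC/dt) qd by differencing the Jacobian along the motion
  Cdot_qd <- ((cjac(q + h * qd) - cjac(q - h * qd)) / (2 * h)) %*% qd
  M <- oracle_mass_matrix(q, p)
  # reuse the numeric Lagrangian pieces for k and gravity
  acc_free <- oracle_recovery_accel(q, qd, Q_total, p)
  rhs_free <- M %*% acc_free          # = Q_total + Qg - k
  A <- rbind(cbind(M, -t(C)), cbind(C, matrix(0, 2, 2)))
  sol <- solve(A, c(rhs_free, -Cdot_qd))
  list(qdd = sol[1:3], lambda = sol[4:5])
}

# random admissible propulsion states (on the closure manifold)
random_propulsion_states <- function(n, p, seed = 1) {
  set.seed(seed)
  rng <- pawsim:::rim_feasible_range(p, margin = 0.05)
  lapply(seq_len(n), function(i) {
    th <- runif(1, rng[1], rng[2])
    ab <- closure_solve(th, p)
    om <- runif(1, -1, 5)
    jj <- chain_jacobian(system_state(ab$alpha, ab$beta, th,
                                      phase = "propulsion"), p)
    system_state(ab$alpha, ab$beta, th,
                 jj$J[1] * om, jj$J[2] * om, om, phase = "propulsion")
  })
}
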