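test_that("dynamics terms match a symbolic Lagrangian derivation", {
  # frozen values from an independent computer-algebra derivation of the
  # equations of motion (kinetic/potential energies of the four bodies,
  # Euler-Lagrange equations), evaluated on a 3 degree ramp with the
  # adopted parameters; "rest" is k + dV/dq at the state
  p <- default_parameters()
  p$ramp_angle <- 0.05
  p$rolling_resistance <- 0
  cases <- list(
    list(s = c(0.53546487410077, 1.85139108897781, -0.567521161841099,
               1.84594834141173, -0.0645056439685436, 0.269979346917727),
         M = matrix(c(0.4230902424, 0.0415696486555932, -0.230895152964601,
                      0.0415696486555932, 0.1298804692, -0.149713977766071,
                      -0.230895152964601, -0.149713977766071, 6.7294900288),
                    3, 3),
         rest = c(-13.1409626070069, 1.71283579791569, 9.29823313634918)),
    list(s = c(1.48310778146133, 0.227597409107484, 0.648781063019178,
               -0.917322660270795, 1.26053932602442, 0.614429939657835),
         M = matrix(c(0.4230902424, 0.0511275498148939, -0.450783173919921,
                      0.0511275498148939, 0.1298804692, -0.0351560145131258,
                      -0.450783173919921, -0.0351560145131258, 6.7294900288),
                    3, 3),
         rest = c(-1.79009185431121, -5.16681085631259, 10.3496694825376)))
  for (cs in cases) {
    s <- cs$s
    st <- system_state(s[1], s[2], s[3], s[4], s[5], s[6])
    dt_ <- dynamics_terms(st, p)
    expect_equal(dt_$M, cs$M, tolerance = 1e-12)
    keg <- applied_forces(st, c(0, 0), 0, p)
    expect_equal(dt_$k - keg, cs$rest, tolerance = 1e-12)
  }
})

test_that("recovery dynamics agree with the numeric-Lagrangian oracle", {
  p <- default_parameters()
  p$ramp_angle <- 0.05
  p$rolling_resistance <- 0   # oracle handles conservative forces only
  set.seed(7)
  worst <- 0
  for (i in 1:100) {
    q <- runif(3, -1, 2.2)
    qd <- runif(3, -3, 3)
    tq <- runif(2, -20, 20)
    st <- system_state(q[1], q[2], q[3], qd[1], qd[2], qd[3])
    ke <- applied_forces(st, tq, 0, p)
    qdd <- recovery_accel(st, ke, p)
    # oracle takes the applied (non-conservative) part only
    Qapp <- c(tq[1] + tq[2], -tq[2], 0)
    qdd_o <- oracle_recovery_accel(q, qd, Qapp, p)
    worst <- max(worst, max(abs(qdd - qdd_o)) / max(1, max(abs(qdd_o))))
  }
  # the oracle itself is finite-difference limited; the frozen symbolic
  # values above pin the dynamics at machine precision
  expect_lt(worst, 1e-5)
})

test_that("equilibrium and scaling properties of the recovery dynamics", {
  p <- default_parameters()
  p$rolling_resistance <- 0
  st <- system_state(pi / 2, pi / 2, 0)   # arms vertical, at rest
  ke <- applied_forces(st, c(0, 0), 0, p)
  expect_equal(recovery_accel(st, ke, p), rep(0, 3), tolerance = 1e-12)
  # doubling every mass and inertia at fixed ke halves the accelerations
  st2 <- system_state(0.8, 1.4, 0.3)
  ke2 <- c(5, -3, 2)
  p2 <- p
  for (f in c("upper_arm_mass", "forearm_mass", "upper_arm_inertia",
              "forearm_inertia", "wheel_inertia", "combined_mass")) {
    p2[[f]] <- 2 * p[[f]]
  }
  expect_equal(recovery_accel(st2, ke2, p2),
               recovery_accel(st2, ke2, p) / 2, tolerance = 1e-12)
})

test_that("generalized forces include slope gravity and rolling resistance", {
  p <- default_parameters()
  st <- system_state(pi / 2, pi / 2, 0, theta_dot = 3)
  ke <- applied_forces(st, c(0, 0), 0, p)
  expect_equal(ke[3], -20 * 0.2988, tolerance = 1e-6)
  expect_equal(ke[1:2], c(0, 0), tolerance = 1e-12)  # arms vertical
  p$ramp_angle <- 3 * pi / 180
  ke_r <- applied_forces(st, c(0, 0), 0, p)
  slope_force <- 72.52 * 9.81 * sin(3 * pi / 180)
  expect_equal(slope_force, 37.24, tolerance = 1e-2)
  expect_equal(ke_r[3], -(20 + slope_force) * 0.2988, tolerance = 1e-6)
  # motor torque enters the wheel coordinate additively
  ke_m <- applied_forces(st, c(0, 0), 7.5, p)
  expect_equal(ke_m[3] - ke_r[3], 7.5)
})

test_that("minimal-form propulsion dynamics equal the multiplier formulation", {
  p <- default_parameters()
  states <- random_propulsion_states(100, p, seed = 11)
  p0 <- p; p0$rolling_resistance <- 0
  worst_impl <- 0
  worst_oracle <- 0
  for (st in states) {
    tq <- runif(2, -20, 20)
    ke <- applied_forces(st, tq, 0, p0)
    tdd <- propulsion_accel(st, ke, p0)
    hr <- hand_reaction(st, tq, 0, p0)
    worst_impl <- max(worst_impl, abs(tdd - hr$qdd[3]) / max(1, abs(tdd)))
    # and against the fully independent numeric multiplier oracle
    q <- c(st$alpha, st$beta, st$theta)
    qd <- c(st$alpha_dot, st$beta_dot, st$theta_dot)
    o <- oracle_propulsion_multiplier(q, qd, c(tq[1] + tq[2], -tq[2], 0), p0)
    worst_oracle <- max(worst_oracle,
                        abs(tdd - o$qdd[3]) / max(1, abs(o$qdd[3])))
  }
  # minimal form vs multiplier form: both analytic, near machine precision
  expect_lt(worst_impl, 1e-8)
  # independent numeric assembly: finite-difference limited (the frozen
  # symbolic values in the first block carry the machine-precision check)
  expect_lt(worst_oracle, 5e-5)
})

test_that("hand reaction is the closure constraint force", {
  p <- default_parameters()
  p$rolling_resistance <- 0
  st <- random_propulsion_states(1, p, seed = 3)[[1]]
  tq <- c(-8, 4)
  hr <- hand_reaction(st, tq, 0, p)
  # action-reaction against the numeric multiplier oracle
  q <- c(st$alpha, st$beta, st$theta)
  qd <- c(st$alpha_dot, st$beta_dot, st$theta_dot)
  o <- oracle_propulsion_multiplier(q, qd, c(tq[1] + tq[2], -tq[2], 0), p)
  expect_equal(hr$force, as.numeric(o$lambda), tolerance = 1e-4)
  # the user torque is the wheel-coordinate share of the constraint force
  expect_equal(hr$tau_p,
               p$pushrim_radius * (hr$force[1] * sin(st$theta) -
                                     hr$force[2] * cos(st$theta)),
               tolerance = 1e-12)
  expect_equal(hr$Ft, hr$tau_p / (2 * p$pushrim_radius))
  # wheel-row balance: tau_p closes the reduced equation of motion
  dt_ <- dynamics_terms(system_state(st$alpha, st$beta, st$theta,
                                     st$alpha_dot, st$beta_dot,
                                     st$theta_dot), p)
  ke <- applied_forces(st, tq, 0, p)
  resid <- dt_$M %*% hr$qdd + dt_$k - ke
  expect_equal(resid[3], hr$tau_p, tolerance = 1e-8)
  # no contact in recovery
  st$phase <- "recovery"
  z <- hand_reaction(st, tq, 0, p)
  expect_identical(c(z$Ft, z$tau_p), c(0, 0))
})

test_that("mechanical energy is conserved in passive recovery", {
  p <- default_parameters()
  p$rolling_resistance <- 0
  y0 <- c(0.9, 1.6, 0, 0.5, -0.8, 0.4)
  rates <- function(t, y, parms) {
    st <- system_state(y[1], y[2], y[3], y[4], y[5], y[6])
    ke <- applied_forces(st, c(0, 0), 0, p)
    list(c(y[4:6], recovery_accel(st, ke, p)))
  }
  tr <- deSolve::ode(y0, seq(0, 1, by = 0.01), rates, NULL,
                     method = "lsoda", rtol = 1e-10, atol = 1e-12)
  E <- apply(tr[, -1], 1, function(y)
    pawsim:::total_energy(system_state(y[1], y[2], y[3], y[4], y[5], y[6]),
                          p))
  expect_lt(max(abs(E - E[1])), 1e-6)
})

test_that("arm swing accelerates the chair early in a passive recovery", {
  # releasing the rim with the arm still moving forward, the backward
  # arm swing pushes the chassis forward: an interval with positive
  # chassis acceleration exists even against rolling resistance
  p <- default_parameters()
  mus <- default_muscles()
  th_r <- -45.3 * pi / 180
  om <- 3.01
  ab <- closure_solve(th_r, p)
  jj <- chain_jacobian(system_state(ab$alpha, ab$beta, th_r,
                                    phase = "propulsion"), p)
  x0 <- c(ab$alpha, ab$alpha - ab$beta, th_r,
          jj$J[1] * om, (jj$J[1] - jj$J[2]) * om, om, 0, 0, 0, 0)
  tr <- forward_simulate(list(list(type = "recovery", tf = 0.3,
                                   u = c(0, 0, 0, 0))),
                         x0, p, mus, dt = 0.005)
  v <- tr[[1]]$x[, 6] * p$wheel_radius
  expect_gt(max(diff(v)), 0)          # acceleration interval exists
  expect_gt(max(v) - v[1], 0.005)     # and is not a numerical artifact
})
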