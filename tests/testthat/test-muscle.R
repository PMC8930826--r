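test_that("activation rate follows the excitation-dependent time constants", {
  expect_equal(activation_rate(0, 1), 1 / 0.020)
  expect_equal(activation_rate(1, 0), -1 / 0.040)
  for (v in c(0, 0.3, 1)) expect_equal(activation_rate(v, v), 0)
  expect_error(activation_rate(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(activation_rate(0.5, 1.2), "\\[0, 1\\]")
})

test_that("activation dynamics match the closed form and stay in [0, 1]", {
  # constant full excitation from rest: a(t) = 1 - exp(-t / Ta)
  tr <- deSolve::ode(0, seq(0, 0.1, by = 0.005),
                     function(t, a, parms) list(activation_rate(a, 1)),
                     NULL, rtol = 1e-12, atol = 1e-12)
  expect_equal(tr[, 2], 1 - exp(-tr[, 1] / 0.020), tolerance = 1e-8)
  # barrier property under an arbitrary measurable excitation
  set.seed(5)
  u_steps <- runif(40)
  ufun <- function(t) u_steps[pmin(40, 1 + floor(t / 0.025))]
  tr2 <- deSolve::ode(c(0, 1), seq(0, 1, by = 0.002),
                      function(t, a, parms)
                        list(activation_rate(a, ufun(t))),
                      NULL, rtol = 1e-10, atol = 1e-10)
  expect_true(all(tr2[, -1] >= -1e-9 & tr2[, -1] <= 1 + 1e-9))
})

test_that("active torque scales with activation and intrinsic curves", {
  mus <- default_muscles()
  for (g in c("se", "sf", "ee", "ef")) {
    expect_equal(active_torque(g, 0, 1.0, 2.0, mus), 0)
    opt <- mus$fl_center[[g]]
    tq <- active_torque(g, 1, opt, 0, mus)
    dir <- if (g %in% c("se", "ef")) 1 else -1
    expect_equal(tq, dir * mus$Tmax[[g]], tolerance = 1e-9)
  }
  # concentric capacity loss: torque-velocity scaling is strictly below
  # one for any shortening rate, and monotone decreasing
  w <- seq(0.1, 11.9, by = 0.2)
  fv <- pawsim:::fv_scale(w, mus)
  expect_true(all(fv < 1))
  expect_true(all(diff(fv) < 0))
  expect_equal(pawsim:::fv_scale(0, mus), 1)
  # eccentric plateau: capacity above isometric, bounded by the plateau
  fe <- pawsim:::fv_scale(seq(-30, -0.1, by = 0.5), mus)
  expect_true(all(fe > 1 & fe <= mus$fv_ecc + 1e-9))
})

test_that("passive torque has a dead zone and engages toward the limits", {
  mus <- default_muscles()
  for (joint in c("shoulder", "elbow")) {
    lim <- if (joint == "shoulder") mus$shoulder_limits else mus$elbow_limits
    mid <- mean(lim)
    expect_lt(abs(passive_torque(joint, mid, mus)), 0.1)
    expect_gt(passive_torque(joint, lim[1], mus), 0)   # pushes up from low
    expect_lt(passive_torque(joint, lim[2], mus), 0)   # pushes down from high
    # strictly monotone (decreasing) everywhere
    ang <- seq(lim[1] - 0.1, lim[2] + 0.1, length.out = 80)
    tq <- vapply(ang, function(a) passive_torque(joint, a, mus), numeric(1))
    expect_true(all(diff(tq) < 0))
  }
})

test_that("net joint torques combine agonist, antagonist and passive parts", {
  mus <- default_muscles()
  st <- system_state(1.6, 0.6, 0)   # mid-range posture, at rest
  tq0 <- net_joint_torques(c(se = 0, sf = 0, ee = 0, ef = 0), st, mus)
  expect_lt(max(abs(tq0)), 0.2)
  # pure shoulder-flexor drive acts in the flexion direction
  # (decreasing alpha); the elbow sees only its passive torque
  tq <- net_joint_torques(c(se = 0, sf = 0.4, ee = 0, ef = 0), st, mus)
  expect_lt(tq[1], tq0[1])
  expect_equal(tq[2], tq0[2])
  # affine in each activation at fixed kinematics
  st2 <- system_state(1.9, 0.8, 0, -1.2, 0.4, 2)
  for (i in 1:4) {
    a0 <- rep(0.2, 4); a1 <- a0; a1[i] <- 0.7; ah <- a0; ah[i] <- 0.45
    t0 <- net_joint_torques(a0, st2, mus)
    t1 <- net_joint_torques(a1, st2, mus)
    th_ <- net_joint_torques(ah, st2, mus)
    expect_equal(th_, (t0 + t1) / 2, tolerance = 1e-10)
  }
})

test_that("muscle parameters round-trip through YAML", {
  mus <- muscle_params(Tmax = c(se = 100, sf = 200, ee = 120, ef = 110),
                       passive_damping = 0.25)
  f <- tempfile(fileext = ".yaml")
  write_muscles(mus, f)
  m2 <- read_muscles(f)
  expect_equal(m2$Tmax, mus$Tmax)
  expect_equal(m2$fl_center, mus$fl_center)
  expect_equal(m2$passive_damping, mus$passive_damping)
  unlink(f)
})
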