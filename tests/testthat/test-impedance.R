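test_that("reference model rate and steady state follow the mass-damper law", {
  imp <- impedance_params(92.50, 14.88)
  Rw <- 0.2988
  expect_equal(reference_rate(1, 0, imp, Rw), -14.88 / 92.50,
               tolerance = 1e-12)
  expect_equal(-14.88 / 92.50, -0.16086, tolerance = 1e-4)
  # steady state under constant torque: vr_inf = tau_p / (Rw Ci)
  vr_inf <- 5.976 / (Rw * 14.88)
  expect_equal(reference_rate(vr_inf, 5.976, imp, Rw), 0, tolerance = 1e-12)
  expect_equal(vr_inf, 1.344, tolerance = 1e-3)
  expect_equal(reference_rate(0, 0, imp, Rw), 0)
  # free decay is exponential with rate Ci/Mi
  tt <- seq(0, 5, by = 0.05)
  tr <- deSolve::ode(1.2, tt, function(t, v, parms)
    list(reference_rate(v, 0, imp, Rw)), NULL, rtol = 1e-11, atol = 1e-12)
  expect_equal(tr[, 2], 1.2 * exp(-14.88 / 92.50 * tt), tolerance = 1e-8)
})

test_that("pole-cancelling PI design yields the prescribed closed loop", {
  Rw <- 0.2988
  for (scales in list(c(1, 1), c(0.5, 1), c(1, 0.5), c(0.5, 0.5))) {
    imp <- impedance_params(92.50, 14.88, scales[1], scales[2])
    pi_c <- design_pi(imp, Rw, tau_cl = 0.02)
    expect_equal(pi_c$Ki / pi_c$Kp, imp$Ci / imp$Mi, tolerance = 1e-12)
    # step response of PI + first-order plant reaches 63.2% at tau_cl
    plant <- function(t, y, parms) {
      # y = (omega, integrator); plant Mi Rw^2 omega' + Ci Rw^2 omega = tau
      err <- 1 - y[1]
      tau <- pi_c$Kp * err + pi_c$Ki * y[2]
      list(c((tau - imp$Ci * Rw^2 * y[1]) / (imp$Mi * Rw^2), err))
    }
    tr <- deSolve::ode(c(0, 0), seq(0, 0.1, by = 1e-4), plant, NULL,
                       rtol = 1e-10, atol = 1e-12)
    om_at_tau <- unname(tr[which.min(abs(tr[, 1] - 0.02)), 2])
    expect_equal(om_at_tau, 1 - exp(-1), tolerance = 0.01)
  }
})

test_that("controller rates implement the PI law on the speed error", {
  pi_c <- design_pi(impedance_params(), 0.2988)
  r <- controller_rates(vr = 0.2988 * 3, integrator = 0, omega = 3,
                        pi_ctrl = pi_c, Rw = 0.2988)
  expect_equal(r$tau_m, 0)
  expect_equal(r$integrator_rate, 0)
  # constant error accumulates Kp e + Ki e t
  e <- 0.4; Tdur <- 1.3
  r2 <- controller_rates(vr = 0.2988 * (3 + e), integrator = e * Tdur,
                         omega = 3, pi_ctrl = pi_c, Rw = 0.2988)
  expect_equal(r2$tau_m, pi_c$Kp * e + pi_c$Ki * e * Tdur, tolerance = 1e-12)
  # disturbance torque passes through
  r3 <- controller_rates(0.2988 * 3, 0, 3, pi_c, 0.2988, tau_d = 5)
  expect_equal(r3$tau_m, 5)
})

test_that("speed loop is stable for all reference-model scale combinations", {
  Rw <- 0.2988
  nominal <- impedance_params(92.50, 14.88)
  pi_c <- design_pi(nominal, Rw, 0.02)
  for (scales in list(c(1, 1), c(0.5, 1), c(1, 0.5), c(0.5, 0.5))) {
    ref <- impedance_params(92.50, 14.88, scales[1], scales[2])
    # states (vr, omega, integrator); plant is the identified model
    A <- rbind(c(-ref$Ci / ref$Mi, 0, 0),
               c(pi_c$Kp / (nominal$Mi * Rw^2) / Rw,
                 -(pi_c$Kp + nominal$Ci * Rw^2) / (nominal$Mi * Rw^2),
                 pi_c$Ki / (nominal$Mi * Rw^2)),
               c(1 / Rw, -1, 0))
    expect_true(all(Re(eigen(A, only.values = TRUE)$values) < 0))
  }
})

test_that("first-order identification recovers known systems", {
  tt <- seq(0, 8, by = 0.02)
  tau <- 6 * (tt < 3) + 2 * (tt >= 5)
  rec <- synthetic_first_order(80, 16, tt, tau, noise_sd = 0)
  fit <- identify_first_order(rec$time, rec$tau_p, rec$v)
  expect_equal(unname(coef(fit)), c(80, 16), tolerance = 1e-6)
  # noisy records: parameters within 5% of the noiseless fit
  noise <- 0.01 * sd(rec$v)
  recn <- synthetic_first_order(80, 16, tt, tau, noise_sd = noise, seed = 9)
  fitn <- identify_first_order(recn$time, recn$tau_p, recn$v)
  expect_lt(max(abs(coef(fitn) - coef(fit)) / coef(fit)), 0.05)
  # degenerate input is rejected
  expect_error(identify_first_order(tt, rep(0, length(tt)), rec$v),
               "identifiability")
  expect_error(identify_first_order(1, 1, 1), "samples")
})

test_that("synthetic first-order records are exact and reproducible", {
  tt <- seq(0, 4, by = 0.01)
  rec <- synthetic_first_order(92.5, 14.88, tt, function(t) rep(8, length(t)))
  a <- 14.88 / 92.5; b <- 8 / (0.2988 * 92.5)
  expect_equal(rec$v, (b / a) * (1 - exp(-a * tt)), tolerance = 1e-10)
  r1 <- synthetic_first_order(80, 16, tt, function(t) sin(t),
                              noise_sd = 0.01, seed = 33)
  r2 <- synthetic_first_order(80, 16, tt, function(t) sin(t),
                              noise_sd = 0.01, seed = 33)
  expect_identical(r1$v, r2$v)
  # median recovery over seeded noisy records stays near the truth
  errs <- vapply(1:30, function(s) {
    rn <- synthetic_first_order(80, 16, seq(0, 8, by = 0.04),
                                function(t) 6 * (t < 3) + 2 * (t >= 5),
                                noise_sd = 0.004, seed = s)
    coef(identify_first_order(rn$time, rn$tau_p, rn$v))[["Mi"]]
  }, numeric(1))
  expect_lt(abs(median(errs) - 80) / 80, 0.02)
})
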