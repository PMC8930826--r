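# Impedance-control assistance loop.
#
# The reference model is a first-order mass-damper
#   Mi dvr/dt + Ci vr = tau_p / Rw,
# mapping the user pushrim torque to a reference wheel speed vr. A PI
# velocity controller designed by pole-zero cancellation on the
# identified first-order plant tracks omega_r = vr / Rw with a
# prescribed closed-loop time constant (default 0.02 s), producing the
# motor torque. Reference-model parameters are identified by
# output-error least squares on the open-loop startup record of the
# nonlinear model.

#' Impedance reference-model parameters
#'
#' @param Mi Apparent mass (kg).
#' @param Ci Apparent damping (N s/m).
#' @param mi_scale,ci_scale Scenario scale factors applied to the
#'   nominal values (1.0 or 0.5 in the study matrix).
#' @return A `paw_impedance` list with the scaled `Mi`, `Ci` and the
#'   scales kept for reporting.
#' @export
impedance_params <- function(Mi = 92.50, Ci = 14.88,
                             mi_scale = 1.0, ci_scale = 1.0) {
  stopifnot(Mi > 0, Ci > 0, mi_scale > 0, ci_scale > 0)
  structure(list(Mi = Mi * mi_scale, Ci = Ci * ci_scale,
                 mi_scale = mi_scale, ci_scale = ci_scale),
            class = "paw_impedance")
}

#' Reference-model rate
#'
#' Time derivative of the reference speed of the mass-damper reference
#' model: `dvr/dt = (tau_p / Rw - Ci vr) / Mi`.
#'
#' @param vr Reference speed (m/s).
#' @param tau_p Bilateral user pushrim torque (N m).
#' @param imp A `paw_impedance` object.
#' @param Rw Wheel radius (m).
#' @return `dvr/dt` (m/s^2).
#' @export
reference_rate <- function(vr, tau_p, imp, Rw) {
  (tau_p / Rw - imp$Ci * vr) / imp$Mi
}

#' PI velocity controller by pole-zero cancellation
#'
#' The controller zero `Ki/Kp` is placed on the identified plant pole
#' `Ci/Mi`; the gain is set so that the reference-to-output closed loop
#' on the identified first-order plant is first order with time constant
#' `tau_cl`. This gives `Kp = Rw^2 Mi / tau_cl`, `Ki = Rw^2 Ci / tau_cl`.
#'
#' @param imp A `paw_impedance` object (the identified plant model).
#' @param Rw Wheel radius (m).
#' @param tau_cl Closed-loop time constant (s).
#' @return A `paw_pi` list with `Kp`, `Ki`, `tau_cl`.
#' @export
design_pi <- function(imp, Rw, tau_cl = 0.02) {
  stopifnot(tau_cl > 0)
  structure(list(Kp = Rw^2 * imp$Mi / tau_cl,
                 Ki = Rw^2 * imp$Ci / tau_cl,
                 tau_cl = tau_cl),
            class = "paw_pi")
}

#' Controller state rates and motor torque
#'
#' PI law on the wheel-speed error: the integrator accumulates
#' `omega_r - omega`; the motor torque is
#' `tau_m = Kp (omega_r - omega) + Ki * integrator + tau_d`.
#'
#' @param vr Reference speed (m/s).
#' @param integrator PI integrator state (rad).
#' @param omega Measured wheel angular rate (rad/s).
#' @param pi_ctrl A `paw_pi` controller.
#' @param Rw Wheel radius (m).
#' @param tau_d Exogenous disturbance torque (N m), default 0.
#' @return List with `integrator_rate` (rad/s) and `tau_m` (N m).
#' @export
controller_rates <- function(vr, integrator, omega, pi_ctrl, Rw,
                             tau_d = 0) {
  omega_r <- vr / Rw
  err <- omega_r - omega
  list(integrator_rate = err,
       tau_m = pi_ctrl$Kp * err + pi_ctrl$Ki * integrator + tau_d)
}

# exact response of the reference model on a sampled torque record,
# first-order-hold on tau_p; used by the identification fit and by the
# synthetic record generator
first_order_response <- function(time, tau_p, Mi, Ci, Rw, v0 = 0) {
  a <- Ci / Mi
  b <- 1 / (Rw * Mi)
  n <- length(time)
  v <- numeric(n)
  v[1] <- v0
  for (k in seq_len(n - 1)) {
    dt <- time[k + 1] - time[k]
    E <- exp(-a * dt)
    u0 <- b * tau_p[k]; u1 <- b * tau_p[k + 1]
    s <- (u1 - u0) / dt
    # v' = -a v + u0 + s t  on [0, dt]
    v[k + 1] <- E * v[k] + (u0 / a) * (1 - E) +
      s * (dt / a - (1 - E) / a^2)
  }
  v
}

#' Identify the first-order reference model from an input-output record
#'
#' Output-error least-squares fit of the single-pole mass-damper model
#' to a pushrim-torque / wheel-speed record: the model response is
#' simulated exactly (first-order hold on the torque input) and the
#' parameters minimizing the sum of squared speed residuals are found by
#' Levenberg-Marquardt from a small multistart grid.
#'
#' @param time Sample times (s), strictly increasing.
#' @param tau_p Bilateral pushrim torque samples (N m).
#' @param v Wheel speed samples (m/s).
#' @param Rw Wheel radius (m).
#' @param v0 Initial speed of the simulated response (m/s).
#' @return An object of class `impedance_fit`: coefficients `Mi`, `Ci`,
#'   the fitted response, residuals, and the record.
#' @export
identify_first_order <- function(time, tau_p, v, Rw = 0.2988, v0 = 0) {
  if (length(time) < 2 || length(tau_p) != length(time) ||
      length(v) != length(time)) {
    stop("need >= 2 samples with matching time/input/output lengths",
         call. = FALSE)
  }
  if (any(diff(time) <= 0)) stop("time grid must be strictly increasing",
                                 call. = FALSE)
  if (max(abs(tau_p)) < 1e-12 || stats::sd(tau_p) < 1e-14) {
    stop("identifiability error: input torque record carries no ",
         "excitation", call. = FALSE)
  }
  resid_fn <- function(par) {
    first_order_response(time, tau_p, exp(par[1]), exp(par[2]), Rw, v0) - v
  }
  # multistart on a coarse log grid of (Mi, Ci)
  starts <- expand.grid(Mi = c(30, 90, 270), Ci = c(5, 15, 45))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = log(as.numeric(starts[i, ])), fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("identification failed to converge", call. = FALSE)
  Mi <- exp(best$par[1]); Ci <- exp(best$par[2])
  fitted <- first_order_response(time, tau_p, Mi, Ci, Rw, v0)
  structure(list(coefficients = c(Mi = Mi, Ci = Ci),
                 time = time, tau_p = tau_p, v = v, Rw = Rw,
                 fitted = fitted, residuals = fitted - v,
                 deviance = best$deviance),
            class = "impedance_fit")
}

#' @export
coef.impedance_fit <- function(object, ...) object$coefficients

#' @export
print.impedance_fit <- function(x, ...) {
  cat("First-order impedance reference model fit (output error)\n")
  cat(sprintf("  apparent mass    Mi = %.2f kg\n", x$coefficients[["Mi"]]))
  cat(sprintf("  apparent damping Ci = %.2f N s/m\n", x$coefficients[["Ci"]]))
  cat(sprintf("  pole Ci/Mi = %.4f 1/s, residual RMS = %.4g m/s on %d samples\n",
              x$coefficients[["Ci"]] / x$coefficients[["Mi"]],
              sqrt(mean(x$residuals^2)), length(x$time)))
  invisible(x)
}

#' @export
residuals.impedance_fit <- function(object, ...) object$residuals

#' Simulated response of a fitted reference model
#'
#' @param object An `impedance_fit`.
#' @param time,tau_p Optional new torque record; defaults to the fitted
#'   record.
#' @param v0 Initial speed (m/s).
#' @param ... Unused.
#' @return Speed response (m/s) on `time`.
#' @export
predict.impedance_fit <- function(object, time = object$time,
                                  tau_p = object$tau_p, v0 = 0, ...) {
  cf <- object$coefficients
  first_order_response(time, tau_p, cf[["Mi"]], cf[["Ci"]], object$Rw, v0)
}
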