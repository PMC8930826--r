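# Forward time-stepping simulation of the user-wheelchair system with
# adaptive-step integration (deSolve). This is the package's independent
# oracle for the collocation solutions: it integrates exactly the same
# rate functions on a phase schedule, handling the propulsion/recovery
# transitions (closure expansion at release, re-grip projection at
# contact).

#' Forward simulation on a phase schedule
#'
#' Integrates the (optionally assisted) dynamics through a sequence of
#' propulsion/recovery phases with prescribed durations and excitation
#' profiles. At a propulsion-to-recovery switch the reduced state is
#' expanded through the closure; at a recovery-to-propulsion switch the
#' hand re-grips the rim: the grip angle is the rim point nearest the
#' hand, and the arm rates are projected onto the closure manifold
#' (velocity consistency with the wheel rate).
#'
#' @param phases List of phases, each a list with `type`
#'   (`"propulsion"`/`"recovery"`), `tf` (duration, s) and `u` (function
#'   of phase-local time returning the 4 excitations, or a constant
#'   vector).
#' @param x0 Initial state of the first phase (reduced layout
#'   `(theta, omega, a_se, a_sf, a_ee, a_ef)` for propulsion, full
#'   10-state layout for recovery; two controller states appended when
#'   `controller` is given).
#' @param params A `paw_params` object.
#' @param muscles A `paw_muscles` object.
#' @param controller Optional list with elements `imp`
#'   ([impedance_params()]) and `pi` ([design_pi()]); enables assistance.
#' @param dt Output sampling interval (s).
#' @param rtol,atol Integration tolerances.
#' @return List of per-phase trajectories (`time` in global seconds,
#'   `x` state matrix, `type`), with attribute `final` (last state).
#' @export
forward_simulate <- function(phases, x0, params, muscles = default_muscles(),
                             controller = NULL, dt = 0.002,
                             rtol = 1e-10, atol = 1e-10) {
  out <- vector("list", length(phases))
  x <- x0
  t0 <- 0
  nxa <- if (is.null(controller)) 0L else 2L
  for (i in seq_along(phases)) {
    ph <- phases[[i]]
    rates <- phase_rates_fn(ph$type, params, muscles, controller)
    ufun <- if (is.function(ph$u)) ph$u else {
      uconst <- rep(ph$u, length.out = 4)
      function(t) uconst
    }
    x <- switch_state(x, ph$type, params, nxa)
    times <- unique(c(seq(0, ph$tf, by = dt), ph$tf))
    dfun <- function(t, y, parms) {
      list(rates(y, pmin(pmax(ufun(t), 0), 1)))
    }
    tr <- deSolve::ode(y = x, times = times, func = dfun, parms = NULL,
                       method = "lsoda", rtol = rtol, atol = atol)
    if (attr(tr, "istate")[1] != 2) {
      stop("integration failed in phase ", i, " (", ph$type,
           ") at t = ", signif(tr[nrow(tr), 1], 4),
           "; last state: ",
           paste(signif(tr[nrow(tr), -1], 4), collapse = ", "),
           call. = FALSE)
    }
    X <- unname(tr[, -1, drop = FALSE])
    out[[i]] <- list(type = ph$type, time = t0 + tr[, 1], x = X)
    x <- X[nrow(X), ]
    t0 <- t0 + ph$tf
  }
  attr(out, "final") <- x
  out
}

# convert the carried state into the layout of the next phase
switch_state <- function(x, type, p, nxa) {
  n <- length(x)
  if (type == "propulsion") {
    if (n == 6L + nxa) return(x)         # already reduced
    # recovery (full) -> propulsion: re-grip at the rim point nearest
    # the hand; wheel rate carries over, arm rates become J * omega
    al <- x[1]; be <- x[1] - x[2]; om <- x[6]
    hx <- p$upper_arm_length * cos(al) + p$forearm_length * cos(be)
    hy <- p$upper_arm_length * sin(al) + p$forearm_length * sin(be)
    thg <- atan2(hy - p$shoulder_offset_v, hx - p$shoulder_offset_h)
    c(thg, om, x[7:10], if (nxa) x[11:12])
  } else {
    if (n == 10L + nxa) return(x)        # already full
    # propulsion (reduced) -> recovery (alpha, elbow flexion angle
    # alpha - beta): expand through the closure
    th <- x[1]; om <- x[2]
    ab <- closure_ab(th, p)
    jj <- chain_jacobian_abt(ab[1], ab[2], th, p)
    c(ab[1], ab[1] - ab[2], th,
      jj$J[1] * om, (jj$J[1] - jj$J[2]) * om, om, x[3:6],
      if (nxa) x[7:8])
  }
}

#' Synthetic first-order input-output record
#'
#' Exact discrete simulation of the mass-damper reference model driven
#' by a torque profile, with seeded Gaussian output noise; the test
#' harness for [identify_first_order()].
#'
#' @param Mi,Ci True apparent mass (kg) and damping (N s/m).
#' @param time Sample times (s), strictly increasing.
#' @param tau_p Torque input samples (N m), or a function of time.
#' @param Rw Wheel radius (m).
#' @param noise_sd Standard deviation of additive output noise (m/s).
#' @param seed Integer seed (reproducible records).
#' @param v0 Initial speed (m/s).
#' @return Data frame with `time`, `tau_p`, `v` plus attributes
#'   `noise_sd` and `seed`.
#' @export
synthetic_first_order <- function(Mi, Ci, time, tau_p, Rw = 0.2988,
                                  noise_sd = 0, seed = 1, v0 = 0) {
  stopifnot(Mi > 0, Ci > 0, all(diff(time) > 0))
  if (is.function(tau_p)) tau_p <- tau_p(time)
  v <- first_order_response(time, tau_p, Mi, Ci, Rw, v0)
  if (noise_sd > 0) {
    rs <- .Random.seed_guard(seed)
    on.exit(rs())
    v <- v + stats::rnorm(length(v), sd = noise_sd)
  }
  structure(data.frame(time = time, tau_p = tau_p, v = v),
            noise_sd = noise_sd, seed = seed)
}

# run code under a temporary RNG state
.Random.seed_guard <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
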