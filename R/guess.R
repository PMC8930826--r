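# Initial-guess construction for the collocation problems: kinematically
# plausible cycles built from typical push/recovery timing, constant or
# ramped wheel speed, closure-consistent arm angles in propulsion, a
# smooth arm return in recovery, and low constant activations.

# grid point fractions (length n_grid) and collocation fractions of a
# phase mesh on [0, 1]
grid_fracs <- function(msh) {
  fr <- 0
  for (s in seq_len(msh$segments)) {
    h <- msh$bounds[s + 1] - msh$bounds[s]
    fr <- c(fr, msh$bounds[s] + h * msh$grid$nodes)
  }
  fr
}

colloc_fracs <- function(msh) grid_fracs(msh)[-1]

smoothstep <- function(s) 3 * s^2 - 2 * s^3
smoothstep_d <- function(s) 6 * s - 6 * s^2

#' Initial guess for a transcribed propulsion problem
#'
#' @param nlp A `paw_nlp` from the transcription step.
#' @param contact,release Guess for the hand contact and release angles
#'   on the pushrim (rad).
#' @param durations Guess for the phase durations (s); defaults to
#'   typical push/recovery times for steady cycles and a ramped split of
#'   the total time for startup.
#' @param activation Constant activation/excitation level of the guess.
#' @return Numeric vector `z0` of decision variables.
#' @export
initial_guess <- function(nlp, contact = -1.92, release = -0.79,
                          durations = NULL, activation = 0.1) {
  p <- nlp$params
  Rw <- p$wheel_radius
  np <- length(nlp$phases)
  steady <- nlp$scenario$kind == "steady"
  v_avg <- nlp$scenario$v_avg
  if (is.null(durations)) {
    durations <- if (steady) c(0.395, 0.545) else {
      Ttot <- nlp$scenario$displacement / v_avg
      fr <- rep(c(0.26, 0.18), length.out = np)
      fr <- fr / sum(fr)
      fr * Ttot
    }
  }
  z0 <- numeric(nlp$nz)
  # wheel-speed profile: constant for steady, ramp from rest for startup
  t_ends <- cumsum(durations)
  om_avg <- v_avg / Rw
  om_at <- function(t) {
    if (steady) return(om_avg)
    Ttot <- t_ends[np]
    # linear ramp to ~1.35x average then flat, area ~ displacement
    tr <- 0.45 * Ttot
    om_pk <- om_avg / (1 - 0.5 * tr / Ttot)
    ifelse(t < tr, om_pk * t / tr, om_pk)
  }
  th_prev_end <- NULL
  for (i in seq_len(np)) {
    ph <- nlp$phases[[i]]
    msh <- ph$mesh
    gf <- grid_fracs(msh)
    tf <- durations[i]
    tglob <- (if (i == 1) 0 else t_ends[i - 1]) + gf * tf
    om <- vapply(tglob, om_at, numeric(1))
    if (ph$type == "propulsion") {
      dth <- cumsum(c(0, (om[-1] + om[-length(om)]) / 2 * diff(gf) * tf))
      # keep the sweep inside the reachable rim window
      rng <- rim_feasible_range(p, margin = 0.05)
      th <- pmin(contact + dth, rng[2])
      X <- cbind(th, om,
                 matrix(activation, length(gf), 4))
      if (nlp$assisted) {
        X <- cbind(X, om * Rw, 0)   # vr tracks the wheel speed, xi = 0
        if (!steady && i == 1) X[1, ncol(X) - 1] <- 0
      }
      th_prev_end <- th[length(th)]
    } else {
      # near-passive ballistic arm swing: integrate the recovery
      # dynamics from the release state with low constant excitation;
      # the arm flies forward-up, gravity reverses it, and it falls
      # back toward the contact posture
      th0 <- if (is.null(th_prev_end)) release else th_prev_end
      ab_rel <- closure_ab(th0, p)
      jj <- chain_jacobian_abt(ab_rel[1], ab_rel[2], th0, p)
      om0 <- om[1]
      x0 <- c(ab_rel[1], ab_rel[1] - ab_rel[2], th0,
              jj$J[1] * om0, (jj$J[1] - jj$J[2]) * om0, om0,
              rep(activation, 4),
              if (nlp$assisted) c(om0 * Rw, 0))
      rates <- phase_rates_fn("recovery", p, nlp$muscles, nlp$controller)
      tr <- tryCatch(
        deSolve::ode(y = x0, times = gf * tf,
                     func = function(t, y, parms) {
                       y[2] <- max(y[2], 0.02)   # keep off the elbow stop
                       list(rates(y, rep(activation, 4)))
                     }, parms = NULL, rtol = 1e-7, atol = 1e-7),
        error = function(e) NULL)
      X <- if (!is.null(tr) && nrow(tr) == length(gf)) {
        unname(tr[, -1, drop = FALSE])
      } else {
        # fall back to a smooth interpolation toward the contact posture
        ab_con <- closure_ab(contact, p)
        s <- smoothstep(gf); sd_ <- smoothstep_d(gf) / tf
        al <- ab_rel[1] + (ab_con[1] - ab_rel[1]) * s
        be <- ab_rel[2] + (ab_con[2] - ab_rel[2]) * s
        dth <- cumsum(c(0, (om[-1] + om[-length(om)]) / 2 * diff(gf) * tf))
        cbind(al, al - be, th0 + dth,
              (ab_con[1] - ab_rel[1]) * sd_,
              (ab_con[1] - ab_rel[1] - ab_con[2] + ab_rel[2]) * sd_,
              om, matrix(activation, length(gf), 4),
              if (nlp$assisted) cbind(om * Rw, 0))
      }
      X[, 2] <- pmax(X[, 2], 0.02)
    }
    z0[ph$Xidx] <- as.numeric(X)
    z0[ph$Uidx] <- activation
    z0[ph$tfidx] <- tf
  }
  z0
}
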