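# Scenario construction and solution of the predictive optimal control
# problems.

#' Scenario configuration of the simulation study
#'
#' Enumerates the study matrix: four locomotion conditions (steady-state
#' or startup, level or 3 degree ramp) times five assistance settings
#' (off, or the four impedance reference-model scale combinations).
#'
#' @param condition One of `"level-steady"`, `"ramp-steady"`,
#'   `"level-startup"`, `"ramp-startup"`.
#' @param assist One of `"off"`, `"m100-c100"`, `"m50-c100"`,
#'   `"m100-c50"`, `"m50-c50"`.
#' @param v_avg Average speed constraint (m/s).
#' @param displacement Startup displacement constraint (m).
#' @param ramp_angle_deg Ramp inclination for ramp conditions (degrees).
#' @return A `paw_scenario` list.
#' @export
build_scenario <- function(condition = c("level-steady", "ramp-steady",
                                         "level-startup", "ramp-startup"),
                           assist = c("off", "m100-c100", "m50-c100",
                                      "m100-c50", "m50-c50"),
                           v_avg = 0.9, displacement = 1.6,
                           ramp_angle_deg = 3) {
  condition <- match.arg(tolower(condition[1]), c(
    "level-steady", "ramp-steady", "level-startup", "ramp-startup"))
  assist <- match.arg(tolower(assist[1]), c(
    "off", "m100-c100", "m50-c100", "m100-c50", "m50-c50"))
  startup <- grepl("startup", condition)
  phase_types <- if (startup) {
    c("propulsion", "recovery", "propulsion", "recovery", "propulsion")
  } else {
    c("propulsion", "recovery")
  }
  scales <- switch(assist,
                   "off" = c(NA, NA),
                   "m100-c100" = c(1, 1),
                   "m50-c100" = c(0.5, 1),
                   "m100-c50" = c(1, 0.5),
                   "m50-c50" = c(0.5, 0.5))
  structure(list(
    condition = condition, assist = assist,
    kind = if (startup) "startup" else "steady",
    phase_types = phase_types,
    v_avg = v_avg, displacement = if (startup) displacement else NA,
    ramp_angle = if (grepl("ramp", condition)) ramp_angle_deg * pi / 180
    else 0,
    mi_scale = scales[1], ci_scale = scales[2]),
    class = "paw_scenario")
}

#' @export
print.paw_scenario <- function(x, ...) {
  cat(sprintf("Scenario: %s, assist %s (%d phases, v_avg %.2f m/s%s)\n",
              x$condition, x$assist, length(x$phase_types), x$v_avg,
              if (!is.na(x$displacement))
                sprintf(", displacement %.2f m", x$displacement) else ""))
  invisible(x)
}

#' Collocation mesh for a scenario
#'
#' The `"fine"` profile matches the mesh density used for the reported
#' study (steady state: 5 polynomials of order 20 per phase; startup:
#' 10 polynomials of order 10 in propulsion, 12 of order 12 in
#' recovery); `"default"` is a coarser mesh adequate for the summary
#' metrics at a fraction of the cost. Segment boundaries are spaced on a
#' Legendre-Gauss-Lobatto distribution to refine near the phase
#' interfaces.
#'
#' @param scenario A `paw_scenario`.
#' @param profile `"default"`, `"fine"`, or a list of per-phase
#'   `list(segments, order)` specs.
#' @return List of per-phase mesh specs.
#' @export
scenario_mesh <- function(scenario, profile = "default") {
  if (is.list(profile)) return(profile)
  lapply(scenario$phase_types, function(ty) {
    if (profile == "fine") {
      if (scenario$kind == "steady") list(segments = 5, order = 20)
      else if (ty == "propulsion") list(segments = 10, order = 10)
      else list(segments = 12, order = 12)
    } else {
      if (scenario$kind == "steady") list(segments = 3, order = 4)
      else if (ty == "propulsion") list(segments = 2, order = 4)
      else list(segments = 3, order = 4)
    }
  })
}

#' Solve a predictive-simulation scenario
#'
#' Transcribes the scenario's multi-phase optimal control problem
#' (minimum integrated squared excitation at the prescribed average
#' speed) by Radau collocation and solves it with the interior-point
#' method. Assisted scenarios embed the closed-loop impedance-control
#' dynamics: the mass-damper reference model (scaled per the assist
#' setting) and the pole-cancelling PI velocity loop designed on the
#' nominal identified model.
#'
#' @param scenario A `paw_scenario` from [build_scenario()].
#' @param params A `paw_params`; its ramp angle is overridden by the
#'   scenario.
#' @param muscles A `paw_muscles`.
#' @param impedance Nominal identified reference-model parameters
#'   (a `paw_impedance`); scenario scales are applied on top.
#' @param mesh Mesh profile (see [scenario_mesh()]).
#' @param guess Optional initial guess: a numeric decision vector or a
#'   previous `paw_solution` with identical structure (continuation).
#' @param tau_cl PI closed-loop time constant (s).
#' @param control Solver options passed to the interior-point method
#'   (e.g. `tol`, `max_iter`, `verbose`).
#' @param presolve When no warm-start guess is supplied, first solve a
#'   pinned variant of the problem (phase durations and hand
#'   contact/release angles restricted to windows around typical
#'   propulsion patterns) at loose tolerance, and use its solution as
#'   the starting point of the free problem. This steers the optimizer
#'   into the physiological wide-arc basin; the reported solution is
#'   always the free problem's.
#' @return A `paw_solution` object.
#' @export
solve_scenario <- function(scenario, params = default_parameters(),
                           muscles = default_muscles(),
                           impedance = impedance_params(),
                           mesh = "default", guess = NULL,
                           tau_cl = 0.02, control = list(),
                           presolve = TRUE) {
  stopifnot(inherits(scenario, "paw_scenario"))
  params$ramp_angle <- scenario$ramp_angle
  validate_paw_params(params)
  controller <- NULL
  if (scenario$assist != "off") {
    imp_ref <- impedance_params(impedance$Mi, impedance$Ci,
                                scenario$mi_scale, scenario$ci_scale)
    controller <- list(imp = imp_ref,
                       pi = design_pi(impedance, params$wheel_radius,
                                      tau_cl))
  }
  mesh_list <- scenario_mesh(scenario, mesh)
  phases <- lapply(scenario$phase_types, function(ty) list(type = ty))
  scen <- list(kind = scenario$kind, v_avg = scenario$v_avg,
               displacement = scenario$displacement)
  nlp <- transcribe(phases, mesh_list, params, muscles, controller, scen)
  opts <- utils::modifyList(list(tol = 1e-6, max_iter = 500), control)
  warm <- FALSE
  z0 <- if (is.null(guess)) {
    zg <- initial_guess(nlp)
    if (presolve) { warm <- TRUE; presolve_guess(nlp, zg, opts) } else zg
  } else if (inherits(guess, "paw_solution")) {
    warm <- TRUE
    if (length(guess$z) == nlp$nz) guess$z
    else map_solution_guess(guess, nlp)
  } else guess
  # warm starts sit close to a solution: begin with a small barrier
  if (warm && is.null(control$mu0)) opts$mu0 <- 1e-3
  res <- solve_nlp(z0, nlp$lb, nlp$ub, nlp$obj, nlp$grad, nlp$con,
                   nlp$jac, nlp$hess, opts)
  as_paw_solution(res, nlp, scenario)
}

# pinned presolve: restrict phase durations and propulsion contact /
# release angles to windows around the typical pattern encoded in the
# initial guess, solve loosely, and return the iterate as a warm start
presolve_guess <- function(nlp, zg, opts) {
  lb <- nlp$lb; ub <- nlp$ub
  for (i in seq_along(nlp$phases)) {
    ph <- nlp$phases[[i]]
    tfg <- zg[ph$tfidx]
    lb[ph$tfidx] <- max(lb[ph$tfidx], 0.85 * tfg)
    ub[ph$tfidx] <- min(ub[ph$tfidx], 1.15 * tfg)
    if (ph$type == "propulsion") {
      G <- ph$mesh$n_grid
      i0 <- ph$Xidx[1, 1]; i1 <- ph$Xidx[G, 1]
      lb[i0] <- max(lb[i0], zg[i0] - 0.12); ub[i0] <- min(ub[i0], zg[i0] + 0.12)
      lb[i1] <- max(lb[i1], zg[i1] - 0.12); ub[i1] <- min(ub[i1], zg[i1] + 0.12)
    }
  }
  pre_opts <- utils::modifyList(opts, list(tol = 1e-4, max_iter = 250))
  res <- tryCatch(
    solve_nlp(zg, lb, ub, nlp$obj, nlp$grad, nlp$con, nlp$jac, nlp$hess,
              pre_opts),
    error = function(e) NULL)
  if (is.null(res) || !all(is.finite(res$z))) zg else res$z
}

# map a solution onto a transcription with a different controller-state
# layout (continuation between unassisted and assisted problems on the
# same mesh): controller states are inserted (vr tracking the wheel
# speed, integrator zero) or dropped
map_solution_guess <- function(sol, nlp) {
  if (length(sol$phases) != length(nlp$phases))
    stop("continuation guess has incompatible structure", call. = FALSE)
  Rw <- nlp$params$wheel_radius
  z0 <- numeric(nlp$nz)
  for (i in seq_along(nlp$phases)) {
    ph <- nlp$phases[[i]]
    sph <- sol$phases[[i]]
    if (nrow(sph$X) != ph$mesh$n_grid || sph$type != ph$type)
      stop("continuation guess has incompatible structure", call. = FALSE)
    X <- sph$X
    oc <- if (ph$type == "propulsion") 2L else 6L
    nb <- if (ph$type == "propulsion") 6L else 10L
    if (ncol(X) == nb && ph$nx == nb + 2L) {
      X <- cbind(X, X[, oc] * Rw, 0)
      if (i == 1L && nlp$scenario$kind == "startup") X[1, nb + 1L] <- 0
    } else if (ncol(X) == nb + 2L && ph$nx == nb) {
      X <- X[, seq_len(nb), drop = FALSE]
    } else if (ncol(X) != ph$nx) {
      stop("continuation guess has incompatible structure", call. = FALSE)
    }
    z0[ph$Xidx] <- as.numeric(X)
    z0[ph$Uidx] <- as.numeric(sph$U)
    z0[ph$tfidx] <- sph$tf
  }
  z0
}

as_paw_solution <- function(res, nlp, scenario) {
  z <- res$z
  phs <- vector("list", length(nlp$phases))
  t0 <- 0
  for (i in seq_along(nlp$phases)) {
    ph <- nlp$phases[[i]]
    tf <- z[ph$tfidx]
    gf <- grid_fracs(ph$mesh)
    phs[[i]] <- list(
      type = ph$type, tf = tf,
      t = t0 + gf * tf,
      tu = t0 + colloc_fracs(ph$mesh) * tf,
      X = matrix(z[ph$Xidx], ph$mesh$n_grid, ph$nx),
      U = matrix(z[ph$Uidx], ph$mesh$n_colloc, nu_ctrl),
      mesh = ph$mesh)
    t0 <- t0 + tf
  }
  sol <- structure(list(
    scenario = scenario, phases = phs, z = z, nlp = nlp,
    objective = res$objective, status = res$status,
    kkt_error = res$kkt_error,
    constraint_violation = res$constraint_violation,
    iterations = res$iterations), class = "paw_solution")
  sol$Wp <- effort_user(sol)
  sol$Wm <- effort_motor(sol)
  sol
}

#' User effort of a solution
#'
#' Radau quadrature of the integrated squared neural excitations over
#' all phases (units s).
#'
#' @param sol A `paw_solution`.
#' @return `Wp` (s).
#' @export
effort_user <- function(sol) {
  total <- 0
  for (ph in sol$phases) {
    w <- point_weights(ph$mesh)
    total <- total + ph$tf * sum(w * rowSums(ph$U^2))
  }
  total
}

#' Motor effort of a solution
#'
#' Radau quadrature of the squared motor torque (units N^2 m^2 s); zero
#' for unassisted solutions.
#'
#' @param sol A `paw_solution`.
#' @return `Wm` (N^2 m^2 s).
#' @export
effort_motor <- function(sol) {
  if (!sol$nlp$assisted) return(0)
  ctrl <- sol$nlp$controller
  Rw <- sol$nlp$params$wheel_radius
  total <- 0
  for (ph in sol$phases) {
    w <- point_weights(ph$mesh)
    Xc <- ph$X[-1, , drop = FALSE]          # states at collocation nodes
    oc <- if (ph$type == "propulsion") 2L else 6L
    vc <- if (ph$type == "propulsion") 7L else 11L
    taum <- ctrl$pi$Kp * (Xc[, vc] / Rw - Xc[, oc]) +
      ctrl$pi$Ki * Xc[, vc + 1L]
    total <- total + ph$tf * sum(w * taum^2)
  }
  total
}

#' @export
print.paw_solution <- function(x, ...) {
  cat(sprintf("Predictive simulation: %s, assist %s [%s]\n",
              x$scenario$condition, x$scenario$assist, x$status))
  durs <- vapply(x$phases, function(p) p$tf, numeric(1))
  cat(sprintf("  phases (%s): %s s, total %.3f s\n",
              paste(substr(vapply(x$phases, `[[`, "", "type"), 1, 1),
                    collapse = "-"),
              paste(sprintf("%.3f", durs), collapse = ", "), sum(durs)))
  cat(sprintf("  Wp = %.4f s", x$Wp))
  if (x$nlp$assisted) cat(sprintf(", Wm = %.2f N^2 m^2 s", x$Wm))
  cat(sprintf("\n  KKT error %.2e, constraint violation %.2e, %d iterations\n",
              x$kkt_error, x$constraint_violation, x$iterations))
  invisible(x)
}

# barycentric Lagrange interpolation from support points xs (values ys,
# possibly a matrix with one column per dimension) to query points xq
lagrange_interp <- function(xs, ys, xq) {
  ys <- as.matrix(ys)
  wb <- vapply(seq_along(xs), function(j) 1 / prod(xs[j] - xs[-j]),
               numeric(1))
  out <- matrix(0, length(xq), ncol(ys))
  for (q in seq_along(xq)) {
    d <- xq[q] - xs
    hit <- which(d == 0)
    if (length(hit)) {
      out[q, ] <- ys[hit[1], ]
    } else {
      ww <- wb / d
      out[q, ] <- colSums(ys * ww) / sum(ww)
    }
  }
  out
}

#' Trajectory outputs of a solution
#'
#' Evaluates the solution on a dense uniform grid (segment-wise Lagrange
#' interpolation of the collocation polynomials) and derives the
#' physical outputs: arm angles (reconstructed through the closure in
#' propulsion), joint torques, user pushrim torque and tangential force,
#' motor torque, and wheel speed.
#'
#' @param sol A `paw_solution`.
#' @param dt Output sampling interval (s).
#' @return Data frame with one row per sample.
#' @export
solution_outputs <- function(sol, dt = 0.002) {
  p <- sol$nlp$params; mus <- sol$nlp$muscles
  ctrl <- sol$nlp$controller
  Rw <- p$wheel_radius
  rows <- list()
  for (i in seq_along(sol$phases)) {
    ph <- sol$phases[[i]]
    msh <- ph$mesh
    gf <- grid_fracs(msh); cf <- colloc_fracs(msh)
    t_loc <- seq(0, ph$tf, by = dt)
    if (t_loc[length(t_loc)] < ph$tf) t_loc <- c(t_loc, ph$tf)
    fr <- t_loc / ph$tf
    X <- matrix(NA_real_, length(fr), ncol(ph$X))
    U <- matrix(NA_real_, length(fr), nu_ctrl)
    ord <- msh$order
    for (s in seq_len(msh$segments)) {
      in_seg <- fr >= msh$bounds[s] - 1e-12 & fr <= msh$bounds[s + 1] + 1e-12
      if (!any(in_seg)) next
      gidx <- ((s - 1) * ord + 1):((s - 1) * ord + ord + 1)
      X[in_seg, ] <- lagrange_interp(gf[gidx], ph$X[gidx, , drop = FALSE],
                                     fr[in_seg])
      cidx <- ((s - 1) * ord + 1):(s * ord)
      # controls have no node at the segment start: evaluate the control
      # polynomial only on the node span and hold the first-node value
      # toward the segment edge (avoids left-edge extrapolation)
      frq <- pmin(pmax(fr[in_seg], cf[cidx[1]]), cf[cidx[ord]])
      U[in_seg, ] <- lagrange_interp(cf[cidx], ph$U[cidx, , drop = FALSE],
                                     frq)
    }
    n <- length(fr)
    df <- data.frame(time = ph$t[1] + t_loc, phase = i, type = ph$type)
    if (ph$type == "propulsion") {
      ab <- t(vapply(X[, 1], function(th) closure_ab(th, p), numeric(2)))
      JJ <- lapply(seq_len(n), function(k)
        chain_jacobian_abt(ab[k, 1], ab[k, 2], X[k, 1], p))
      df$alpha <- ab[, 1]; df$beta <- ab[, 2]
      df$theta <- X[, 1]; df$omega <- X[, 2]
      df$alpha_dot <- vapply(seq_len(n), function(k)
        JJ[[k]]$J[1] * X[k, 2], numeric(1))
      df$beta_dot <- vapply(seq_len(n), function(k)
        JJ[[k]]$J[2] * X[k, 2], numeric(1))
      acts <- X[, 3:6, drop = FALSE]
      cs <- if (sol$nlp$assisted) X[, 7:8, drop = FALSE] else NULL
    } else {
      # recovery states carry (alpha, elbow flexion angle)
      df$alpha <- X[, 1]; df$beta <- X[, 1] - X[, 2]
      df$theta <- X[, 3]; df$omega <- X[, 6]
      df$alpha_dot <- X[, 4]; df$beta_dot <- X[, 4] - X[, 5]
      acts <- X[, 7:10, drop = FALSE]
      cs <- if (sol$nlp$assisted) X[, 11:12, drop = FALSE] else NULL
    }
    colnames(acts) <- paste0("a_", c("se", "sf", "ee", "ef"))
    df <- cbind(df, acts)
    colnames(U) <- paste0("u_", c("se", "sf", "ee", "ef"))
    df <- cbind(df, U)
    df$v <- df$omega * Rw
    # joint torques
    tq <- t(vapply(seq_len(n), function(k)
      net_torques_core(acts[k, ], df$alpha[k], df$beta[k],
                       df$alpha_dot[k], df$beta_dot[k], mus), numeric(2)))
    df$tau_shoulder <- tq[, 1]; df$tau_elbow <- tq[, 2]
    # motor torque
    if (sol$nlp$assisted) {
      df$vr <- cs[, 1]
      df$tau_m <- ctrl$pi$Kp * (cs[, 1] / Rw - df$omega) +
        ctrl$pi$Ki * cs[, 2]
    } else {
      df$vr <- NA_real_
      df$tau_m <- 0
    }
    # hand reaction (propulsion only)
    df$tau_p <- 0; df$Ft <- 0
    if (ph$type == "propulsion") {
      for (k in seq_len(n)) {
        ke <- applied_forces_core(df$alpha[k], df$beta[k], df$omega[k],
                                  tq[k, 1], tq[k, 2], df$tau_m[k], p)
        srl <- propulsion_multiplier_core(df$alpha[k], df$beta[k],
                                          df$theta[k], df$alpha_dot[k],
                                          df$beta_dot[k], df$omega[k],
                                          ke, p)
        df$tau_p[k] <- p$pushrim_radius *
          (srl$lambda[1] * sin(df$theta[k]) -
             srl$lambda[2] * cos(df$theta[k]))
      }
      df$Ft <- df$tau_p / (2 * p$pushrim_radius)
    }
    rows[[i]] <- df
  }
  do.call(rbind, rows)
}

#' Archive a solution / export resampled trajectories
#'
#' `write_solution` stores the per-phase collocation grids, states,
#' controls, durations, efforts and solver diagnostics as JSON;
#' `write_solution_csv` exports the uniformly resampled trajectory
#' outputs (default 1 kHz) for plotting.
#'
#' @param sol A `paw_solution`.
#' @param path Output file path.
#' @param dt Resampling interval for the CSV export (s).
#' @return The path, invisibly.
#' @export
write_solution <- function(sol, path) {
  arch <- list(
    scenario = unclass(sol$scenario),
    status = sol$status, kkt_error = sol$kkt_error,
    iterations = sol$iterations, Wp = sol$Wp, Wm = sol$Wm,
    phases = lapply(sol$phases, function(ph) list(
      type = ph$type, tf = ph$tf, t = ph$t, tu = ph$tu,
      X = unname(as.matrix(ph$X)), U = unname(as.matrix(ph$U)))))
  jsonlite::write_json(arch, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_solution
#' @export
write_solution_csv <- function(sol, path, dt = 0.001) {
  utils::write.csv(solution_outputs(sol, dt = dt), path,
                   row.names = FALSE)
  invisible(path)
}

#' @export
plot.paw_solution <- function(x, ...) {
  out <- solution_outputs(x)
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(out$time, out$v, type = "l", xlab = "time (s)",
                 ylab = "wheel speed (m/s)",
                 main = sprintf("%s / %s", x$scenario$condition,
                                x$scenario$assist))
  pb <- cumsum(vapply(x$phases, function(p) p$tf, numeric(1)))
  graphics::abline(v = pb, lty = 3, col = "grey50")
  graphics::plot(out$time, out$tau_p, type = "l", xlab = "time (s)",
                 ylab = "user torque (N m)")
  graphics::abline(v = pb, lty = 3, col = "grey50")
  graphics::plot(out$time, out$tau_m, type = "l", xlab = "time (s)",
                 ylab = "motor torque (N m)")
  graphics::abline(v = pb, lty = 3, col = "grey50")
  invisible(out)
}
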