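# Sparse primal-dual interior-point solver for equality-constrained
# nonlinear programs with box bounds:
#
#     min f(z)   s.t.  c(z) = 0,  lb <= z <= ub.
#
# Standard log-barrier treatment of the bounds with a monotone
# (Fiacco-McCormick) barrier schedule, Newton steps on the primal-dual
# system with inertia-free regularization (curvature test on the primal
# block), fraction-to-the-boundary rule, and an l1 merit line search.
# Derivatives are supplied by the caller: gradient and sparse Jacobian
# are exact; the Hessian callback returns the Hessian of the Lagrangian
# (exact or Gauss-Newton, at the transcription's choice).
#
# This is deliberately a compact, deterministic solver: identical
# inputs, tolerances and iteration limits reproduce identical iterates.

solve_nlp <- function(z0, lb, ub, obj, grad, con, jac, hess,
                      opts = list()) {
  o <- utils::modifyList(list(
    tol = 1e-6, mu0 = 1e-1, mu_min = 1e-9, kappa_eps = 10,
    kappa_mu = 0.2, theta_mu = 1.5, tau_min = 0.99,
    max_iter = 600, max_ls = 25, delta0 = 1e-8, delta_max = 1e10,
    push_pad = 1e-2, verbose = FALSE), opts)

  n <- length(z0)
  has_lb <- is.finite(lb)
  has_ub <- is.finite(ub)

  # push the start strictly inside the bounds (smaller pads preserve
  # warm starts whose active set is already correct)
  z <- z0
  pad <- o$push_pad
  i <- has_lb & (z < lb + pad * pmax(1, abs(lb)))
  z[i] <- (lb + pad * pmax(1, abs(lb)))[i]
  i <- has_ub & (z > ub - pad * pmax(1, abs(ub)))
  z[i] <- (ub - pad * pmax(1, abs(ub)))[i]
  bad <- has_lb & has_ub & (ub - lb < 4 * pad)
  z[bad] <- (lb[bad] + ub[bad]) / 2

  cz <- con(z)
  m <- length(cz)
  lam <- rep(0, m)
  mu <- o$mu0
  zL <- ifelse(has_lb, pmax(mu / pmax(z - lb, 1e-8), 1e-8), 0)
  zU <- ifelse(has_ub, pmax(mu / pmax(ub - z, 1e-8), 1e-8), 0)

  fz <- obj(z); gz <- grad(z); Jz <- jac(z)
  filter_th <- numeric(0); filter_ph <- numeric(0)
  delta_last <- 0
  status <- "max_iter"
  iter_out <- 0

  kkt_error <- function(gz, Jz, lam, zL, zU, cz, z, mu_) {
    dual <- gz - as.numeric(Matrix::crossprod(Jz, lam)) - zL + zU
    sd <- max(1, (sum(abs(lam)) + sum(zL) + sum(zU)) / max(1, m + n) / 100)
    comp <- 0
    if (any(has_lb)) comp <- max(comp, max(abs(zL[has_lb] * (z - lb)[has_lb] - mu_)))
    if (any(has_ub)) comp <- max(comp, max(abs(zU[has_ub] * (ub - z)[has_ub] - mu_)))
    max(max(abs(dual)) / sd, if (m) max(abs(cz)) else 0, comp / sd)
  }

  for (iter in seq_len(o$max_iter)) {
    iter_out <- iter
    E0 <- kkt_error(gz, Jz, lam, zL, zU, cz, z, 0)
    if (E0 <= o$tol) { status <- "success"; break }
    Emu <- kkt_error(gz, Jz, lam, zL, zU, cz, z, mu)
    if (Emu <= o$kappa_eps * mu && mu > o$mu_min) {
      mu <- max(o$tol / 20, min(o$kappa_mu * mu, mu^o$theta_mu))
      filter_th <- numeric(0); filter_ph <- numeric(0)
      next
    }

    # project bound multipliers toward mu-complementarity (kappa-Sigma
    # safeguard, keeps the barrier Hessian well conditioned)
    kS <- 1e10
    if (any(has_lb)) {
      sl <- pmax(z - lb, 1e-12)
      zL <- ifelse(has_lb, pmin(pmax(zL, mu / (kS * sl)), kS * mu / sl), zL)
    }
    if (any(has_ub)) {
      su <- pmax(ub - z, 1e-12)
      zU <- ifelse(has_ub, pmin(pmax(zU, mu / (kS * su)), kS * mu / su), zU)
    }

    H <- hess(z, lam)
    sigma <- ifelse(has_lb, zL / pmax(z - lb, 1e-12), 0) +
      ifelse(has_ub, zU / pmax(ub - z, 1e-12), 0)
    # barrier gradient of the primal-dual residual
    r_dual <- gz - as.numeric(Matrix::crossprod(Jz, lam)) -
      ifelse(has_lb, mu / pmax(z - lb, 1e-12), 0) +
      ifelse(has_ub, mu / pmax(ub - z, 1e-12), 0)

    delta <- if (delta_last > 0) max(o$delta0, delta_last / 3) else 0
    dz <- NULL
    repeat {
      KKT <- rbind(
        cbind(H + Matrix::Diagonal(n, sigma + delta), Matrix::t(Jz)),
        cbind(Jz, Matrix::Diagonal(m, -1e-10)))
      rhs <- c(-r_dual, -cz)
      sol <- tryCatch(as.numeric(Matrix::solve(KKT, rhs)),
                      error = function(e) NULL)
      ok <- !is.null(sol) && all(is.finite(sol))
      if (ok) {
        dz <- sol[seq_len(n)]
        dnu <- sol[n + seq_len(m)]
        # inertia-free curvature test on the primal block: only reject
        # clearly negative curvature directions
        curv <- sum(dz * as.numeric(H %*% dz)) + sum((sigma + delta) * dz^2)
        ok <- curv >= -1e-9 * sum(dz^2)
      }
      if (ok) break
      delta <- if (delta == 0) max(o$delta0, 1e-4) else delta * 10
      if (delta > o$delta_max) { status <- "regularization_failure"; break }
    }
    if (!is.null(status) && status == "regularization_failure") break
    delta_last <- delta
    dlam <- -dnu
    lam_new_full <- lam + dlam

    # bound multiplier steps (primal-dual)
    dzL <- ifelse(has_lb, (mu - zL * dz) / pmax(z - lb, 1e-12) - zL, 0)
    dzU <- ifelse(has_ub, (mu + zU * dz) / pmax(ub - z, 1e-12) - zU, 0)

    # fraction to the boundary
    tau <- max(o$tau_min, 1 - mu)
    a_pri <- 1
    if (any(has_lb & (dz < 0))) {
      i <- has_lb & (dz < 0)
      a_pri <- min(a_pri, min(-tau * (z - lb)[i] / dz[i]))
    }
    if (any(has_ub & (dz > 0))) {
      i <- has_ub & (dz > 0)
      a_pri <- min(a_pri, min(tau * (ub - z)[i] / dz[i]))
    }
    a_dual <- 1
    if (any(has_lb & (dzL < 0))) {
      i <- has_lb & (dzL < 0)
      a_dual <- min(a_dual, min(-tau * zL[i] / dzL[i]))
    }
    if (any(has_ub & (dzU < 0))) {
      i <- has_ub & (dzU < 0)
      a_dual <- min(a_dual, min(-tau * zU[i] / dzU[i]))
    }

    # l1 merit line search
    barrier <- function(zv) {
      b <- 0
      if (any(has_lb)) {
        s <- (zv - lb)[has_lb]
        if (any(s <= 0)) return(Inf)
        b <- b - mu * sum(log(s))
      }
      if (any(has_ub)) {
        s <- (ub - zv)[has_ub]
        if (any(s <= 0)) return(Inf)
        b <- b - mu * sum(log(s))
      }
      b
    }
    theta0 <- sum(abs(cz))
    phib0 <- fz + barrier(z)
    dphib <- sum((gz - ifelse(has_lb, mu / pmax(z - lb, 1e-12), 0) +
                    ifelse(has_ub, mu / pmax(ub - z, 1e-12), 0)) * dz)
    g_th <- 1e-5; g_ph <- 1e-5
    alpha <- a_pri
    accepted <- FALSE
    ftype_step <- FALSE
    for (ls in seq_len(o$max_ls)) {
      z_try <- z + alpha * dz
      f_try <- tryCatch(obj(z_try), error = function(e) Inf)
      c_try <- tryCatch(con(z_try), error = function(e) NULL)
      if (!is.null(c_try) && is.finite(f_try) && all(is.finite(c_try))) {
        phib_try <- f_try + barrier(z_try)
        theta_try <- sum(abs(c_try))
        if (is.finite(phib_try)) {
          # acceptable to the filter?
          filt_ok <- TRUE
          if (length(filter_th)) {
            filt_ok <- all(theta_try <= (1 - g_th) * filter_th |
                             phib_try <= filter_ph - g_ph * filter_th)
          }
          if (filt_ok) {
            switching <- dphib < 0 &&
              alpha * (-dphib)^2.3 > 1 * theta0^1.1
            if (switching) {
              if (phib_try <= phib0 + 1e-4 * alpha * dphib) {
                accepted <- TRUE; ftype_step <- TRUE; break
              }
            } else {
              if (theta_try <= (1 - g_th) * theta0 + 1e-15 ||
                  phib_try <= phib0 - g_ph * theta0 +
                    1e-12 * max(1, abs(phib0))) {
                accepted <- TRUE; break
              }
            }
          }
        }
      }
      alpha <- alpha / 2
    }
    if (accepted && !ftype_step) {
      # augment the filter so this region is not revisited
      filter_th <- c(filter_th, (1 - g_th) * theta0)
      filter_ph <- c(filter_ph, phib0 - g_ph * theta0)
    }
    if (!accepted) {
      # fall back to a tiny step; if even that fails, regularize harder
      alpha <- min(a_pri, 1e-8)
      z_try <- z + alpha * dz
      c_try <- tryCatch(con(z_try), error = function(e) NULL)
      f_try <- tryCatch(obj(z_try), error = function(e) Inf)
      if (is.null(c_try) || !is.finite(f_try) || !all(is.finite(c_try))) {
        delta_last <- max(delta_last * 100, 1e-4)
        next
      }
    }

    z <- z_try
    lam <- lam + alpha * dlam
    zL <- pmax(zL + a_dual * dzL, 1e-12)
    zU <- pmax(zU + a_dual * dzU, 1e-12)
    cz <- con(z); fz <- obj(z); gz <- grad(z); Jz <- jac(z)

    if (o$verbose) {
      message(sprintf(
        "it %3d  mu %.1e  f %.6g  |c| %.2e  E0 %.2e  a %.1e  d %.1e %s",
        iter, mu, fz, if (m) max(abs(cz)) else 0, E0, alpha, delta,
        if (accepted) "" else "r"))
    }
  }

  list(z = z, lambda = lam, zL = zL, zU = zU,
       objective = fz, constraint_violation = if (m) max(abs(cz)) else 0,
       kkt_error = kkt_error(gz, Jz, lam, zL, zU, cz, z, 0),
       iterations = iter_out, status = status, mu = mu)
}
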