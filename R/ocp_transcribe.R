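# Multi-phase Radau pseudospectral transcription of the propulsion
# optimal control problems.
#
# Phases alternate propulsion (reduced coordinates theta, omega plus four
# activations; arm angles reconstructed through the closure) and recovery
# (full three-degree-of-freedom coordinates plus activations). Assisted
# problems append the controller states (vr, xi). Phase durations are
# free decision variables; each phase is transcribed on [0, 1] and scaled
# by its duration. Collocation defects, inter-phase continuity with
# closure and velocity-level closure at every propulsion entry, and the
# scenario constraints (periodicity / average speed for steady state;
# rest start, displacement and total time for startup) form the equality
# constraint set. Objective and constraint first derivatives are exact
# (analytic structure plus complex-step dynamics Jacobians); the
# Lagrangian Hessian is exact to finite-difference accuracy.

nu_ctrl <- 4L

# ---- phase dynamics ---------------------------------------------------

# returns a complex-step-safe rates function for one phase
phase_rates_fn <- function(type, params, muscles, controller = NULL) {
  p <- params; mus <- muscles
  assisted <- !is.null(controller)
  Ta <- mus$Ta; Td <- mus$Td
  Rw <- p$wheel_radius
  if (assisted) {
    Kp <- controller$pi$Kp; Ki <- controller$pi$Ki
    Mi <- controller$imp$Mi; Ci <- controller$imp$Ci
  }
  if (type == "propulsion") {
    function(x, u) {
      theta <- x[1]; om <- x[2]; a <- x[3:6]
      ab <- closure_ab(theta, p)
      jj <- chain_jacobian_abt(ab[1], ab[2], theta, p)
      ad <- jj$J[1] * om; bd <- jj$J[2] * om
      tau <- net_torques_core(a, ab[1], ab[2], ad, bd, mus)
      adot <- (u - a) * (u / Ta + (1 - u) / Td)
      if (!assisted) {
        ke <- applied_forces_core(ab[1], ab[2], om, tau[1], tau[2], 0, p)
        dt_ <- dyn_terms(ab[1], ab[2], ad, bd, p)
        J <- jj$J
        MJ <- dt_$M %*% J
        m_red <- J[1] * MJ[1] + J[2] * MJ[2] + J[3] * MJ[3]
        dJdt <- jj$dJ * om
        rhs <- sum(J * (ke - dt_$k - dt_$M %*% (dJdt * om)))
        c(om, rhs / m_red, adot)
      } else {
        vr <- x[7]; xi <- x[8]
        err <- vr / Rw - om
        taum <- Kp * err + Ki * xi
        ke <- applied_forces_core(ab[1], ab[2], om, tau[1], tau[2], taum, p)
        sol <- propulsion_multiplier_core(ab[1], ab[2], theta, ad, bd, om,
                                          ke, p)
        taup <- p$pushrim_radius *
          (sol$lambda[1] * sin(theta) - sol$lambda[2] * cos(theta))
        c(om, sol$qdd[3], adot,
          (taup / Rw - Ci * vr) / Mi, err)
      }
    }
  } else {
    # recovery states use (shoulder angle alpha, elbow flexion angle
    # el = alpha - beta) so the elbow range is a plain box bound
    function(x, u) {
      al <- x[1]; el <- x[2]; ald <- x[4]; eld <- x[5]; om <- x[6]
      be <- al - el; bd <- ald - eld
      a <- x[7:10]
      tau <- net_torques_core(a, al, be, ald, bd, mus)
      adot <- (u - a) * (u / Ta + (1 - u) / Td)
      taum <- 0
      if (assisted) {
        vr <- x[11]; xi <- x[12]
        err <- vr / Rw - om
        taum <- Kp * err + Ki * xi
      }
      ke <- applied_forces_core(al, be, om, tau[1], tau[2], taum, p)
      dt_ <- dyn_terms(al, be, ald, bd, p)
      qdd <- solve(dt_$M, ke - dt_$k)
      if (!assisted) {
        c(ald, eld, om, qdd[1], qdd[1] - qdd[2], qdd[3], adot)
      } else {
        c(ald, eld, om, qdd[1], qdd[1] - qdd[2], qdd[3], adot,
          -Ci * vr / Mi, err)   # tau_p = 0 in recovery
      }
    }
  }
}

# complex-step Jacobian of a rates function at (x, u): nx x (nx + nu)
cs_rates_jac <- function(fn, x, u, nf) {
  nx <- length(x); nu <- length(u)
  A <- matrix(0, nf, nx + nu)
  h <- 1e-20
  for (j in seq_len(nx)) {
    xc <- as.complex(x); xc[j] <- xc[j] + h * 1i
    A[, j] <- Im(fn(xc, as.complex(u))) / h
  }
  for (j in seq_len(nu)) {
    uc <- as.complex(u); uc[j] <- uc[j] + h * 1i
    A[, nx + j] <- Im(fn(as.complex(x), uc)) / h
  }
  A
}

# ---- mesh handling ----------------------------------------------------

# per-phase mesh: segment boundaries (LGL-spaced by default, to refine
# near the phase interfaces) and a Radau grid per segment
build_phase_mesh <- function(segments, order, spacing = c("lgl", "uniform")) {
  spacing <- match.arg(spacing)
  bounds <- if (spacing == "lgl") lgl_points(segments + 1) else
    seq(0, 1, length.out = segments + 1)
  g <- radau_grid(order)
  list(segments = segments, order = order, bounds = bounds, grid = g,
       n_colloc = segments * order, n_grid = segments * order + 1)
}

# ---- transcription ----------------------------------------------------

transcribe <- function(phases, mesh, params, muscles, controller = NULL,
                       scenario = list(kind = "steady", v_avg = 0.9),
                       bounds_cfg = list()) {
  assisted <- !is.null(controller)
  np <- length(phases)
  nxa <- if (assisted) 2L else 0L
  nx_of <- function(type) if (type == "propulsion") 6L + nxa else 10L + nxa

  bc <- utils::modifyList(list(
    omega = c(-2, 12), rate = c(-25, 25),
    vr = c(-2, 8), xi = c(-20, 20), tf = c(0.05, 3),
    theta_margin = 0.03), bounds_cfg)
  th_rng <- rim_feasible_range(params, margin = bc$theta_margin)
  al_rng <- muscles$shoulder_limits
  el_rng <- muscles$elbow_limits

  # --- variable layout ---
  ptr <- 0L
  ph_info <- vector("list", np)
  for (i in seq_len(np)) {
    type <- phases[[i]]$type
    nx <- nx_of(type)
    msh <- build_phase_mesh(mesh[[i]]$segments, mesh[[i]]$order,
                            if (is.null(mesh[[i]]$spacing)) "lgl"
                            else mesh[[i]]$spacing)
    G <- msh$n_grid; C <- msh$n_colloc
    Xidx <- matrix(ptr + seq_len(G * nx), G, nx); ptr <- ptr + G * nx
    Uidx <- matrix(ptr + seq_len(C * nu_ctrl), C, nu_ctrl)
    ptr <- ptr + C * nu_ctrl
    tfidx <- ptr + 1L; ptr <- ptr + 1L
    ph_info[[i]] <- list(type = type, nx = nx, mesh = msh,
                         Xidx = Xidx, Uidx = Uidx, tfidx = tfidx,
                         rates = phase_rates_fn(type, params, muscles,
                                                controller))
  }
  nz <- ptr

  # --- bounds ---
  lb <- rep(-Inf, nz); ub <- rep(Inf, nz)
  for (ph in ph_info) {
    if (ph$type == "propulsion") {
      lb[ph$Xidx[, 1]] <- th_rng[1]; ub[ph$Xidx[, 1]] <- th_rng[2]
      lb[ph$Xidx[, 2]] <- bc$omega[1]; ub[ph$Xidx[, 2]] <- bc$omega[2]
      acols <- 3:6
    } else {
      lb[ph$Xidx[, 1]] <- al_rng[1]; ub[ph$Xidx[, 1]] <- al_rng[2]
      lb[ph$Xidx[, 2]] <- el_rng[1]; ub[ph$Xidx[, 2]] <- el_rng[2]
      for (cc in 4:5) { lb[ph$Xidx[, cc]] <- bc$rate[1]
                        ub[ph$Xidx[, cc]] <- bc$rate[2] }
      lb[ph$Xidx[, 6]] <- bc$omega[1]; ub[ph$Xidx[, 6]] <- bc$omega[2]
      acols <- 7:10
    }
    for (cc in acols) { lb[ph$Xidx[, cc]] <- 0; ub[ph$Xidx[, cc]] <- 1 }
    if (assisted) {
      vc <- max(acols) + 1L
      lb[ph$Xidx[, vc]] <- bc$vr[1]; ub[ph$Xidx[, vc]] <- bc$vr[2]
      lb[ph$Xidx[, vc + 1L]] <- bc$xi[1]; ub[ph$Xidx[, vc + 1L]] <- bc$xi[2]
    }
    lb[ph$Uidx] <- 0; ub[ph$Uidx] <- 1
    lb[ph$tfidx] <- bc$tf[1]; ub[ph$tfidx] <- bc$tf[2]
  }

  # --- constraint layout: defects, then links, then globals ---
  crow <- 0L
  for (i in seq_len(np)) {
    ph <- ph_info[[i]]
    ph_info[[i]]$defect_row0 <- crow
    crow <- crow + ph$mesh$n_colloc * ph$nx
  }
  # links between consecutive phases + (steady) wrap link R(end)->P(start)
  link_defs <- list()
  add_link <- function(defs, from, to, wrap) {
    c(defs, list(list(from = from, to = to, wrap = wrap)))
  }
  for (i in seq_len(np - 1)) {
    link_defs <- add_link(link_defs, i, i + 1, FALSE)
  }
  steady <- scenario$kind == "steady"
  if (steady) link_defs <- add_link(link_defs, np, 1, TRUE)

  links <- list()
  for (ld in link_defs) {
    phF <- ph_info[[ld$from]]; phT <- ph_info[[ld$to]]
    GF <- phF$mesh$n_grid
    xF_idx <- phF$Xidx[GF, ]; xT_idx <- phT$Xidx[1, ]
    vidx <- c(xF_idx, xT_idx)
    nF <- phF$nx
    p <- params
    if (phF$type == "propulsion") {
      # propulsion -> recovery: expand reduced end state into the full
      # recovery start state via closure and velocity-level closure
      fn <- local({
        nF <- nF; p <- p; nxa <- nxa; nT <- length(xT_idx)
        function(v) {
          xF <- v[seq_len(nF)]; xT <- v[nF + seq_len(nT)]
          thF <- xF[1]; omF <- xF[2]
          alT <- xT[1]; beT <- xT[1] - xT[2]
          cres <- closure_residual_abt(alT, beT, thF, p)
          jj <- chain_jacobian_abt(alT, beT, thF, p)
          r <- c(cres,
                 xT[4] - jj$J[1] * omF,
                 (xT[4] - xT[5]) - jj$J[2] * omF,
                 xT[3] - thF,
                 xT[6] - omF,
                 xT[7:10] - xF[3:6])
          if (nxa) r <- c(r, xT[11:12] - xF[7:8])
          r
        }
      })
      nr <- 10L + nxa
    } else {
      # recovery -> propulsion: hand re-grips the rim; closure and
      # velocity closure at the new contact angle, wheel rate and
      # activations continuous (theta itself resets to the rim angle)
      fn <- local({
        nF <- nF; p <- p; nxa <- nxa; nT <- length(xT_idx)
        function(v) {
          xF <- v[seq_len(nF)]; xT <- v[nF + seq_len(nT)]
          alF <- xF[1]; beF <- xF[1] - xF[2]
          thT <- xT[1]; omT <- xT[2]
          cres <- closure_residual_abt(alF, beF, thT, p)
          jj <- chain_jacobian_abt(alF, beF, thT, p)
          r <- c(cres,
                 xF[4] - jj$J[1] * omT,
                 (xF[4] - xF[5]) - jj$J[2] * omT,
                 omT - xF[6],
                 xT[3:6] - xF[7:10])
          if (nxa) r <- c(r, xT[7:8] - xF[11:12])
          r
        }
      })
      nr <- 9L + nxa
    }
    links[[length(links) + 1]] <- list(fn = fn, vidx = vidx, nr = nr,
                                       row0 = crow)
    crow <- crow + nr
  }

  # --- global linear constraints ---
  glin_i <- integer(0); glin_j <- integer(0); glin_x <- numeric(0)
  glin_rhs <- numeric(0)
  add_lin <- function(cols, vals, rhs) {
    k <- length(glin_rhs) + 1L
    glin_i <<- c(glin_i, rep(k, length(cols)))
    glin_j <<- c(glin_j, cols)
    glin_x <<- c(glin_x, vals)
    glin_rhs <<- c(glin_rhs, rhs)
  }
  Rw <- params$wheel_radius
  th_first <- integer(np); th_last <- integer(np)
  for (i in seq_len(np)) {
    ph <- ph_info[[i]]
    tc <- if (ph$type == "propulsion") 1L else 3L
    th_first[i] <- ph$Xidx[1, tc]
    th_last[i] <- ph$Xidx[ph$mesh$n_grid, tc]
  }
  tf_all <- vapply(ph_info, function(ph) as.integer(ph$tfidx), integer(1))
  if (steady) {
    # average speed: Rw * total wheel rotation = v_avg * cycle time
    add_lin(c(th_last, th_first, tf_all),
            c(rep(Rw, np), rep(-Rw, np), rep(-scenario$v_avg, np)), 0)
  } else {
    add_lin(c(th_last, th_first),
            c(rep(Rw, np), rep(-Rw, np)), scenario$displacement)
    add_lin(tf_all, rep(1, np),
            scenario$displacement / scenario$v_avg)
    # start from rest
    add_lin(ph_info[[1]]$Xidx[1, 2], 1, 0)
    if (assisted) {
      add_lin(ph_info[[1]]$Xidx[1, 7], 1, 0)   # vr(0) = 0
      add_lin(ph_info[[1]]$Xidx[1, 8], 1, 0)   # xi(0) = 0
    }
  }
  glin_row0 <- crow
  m_total <- crow + length(glin_rhs)
  Glin <- if (length(glin_rhs)) {
    Matrix::sparseMatrix(i = glin_i, j = glin_j, x = glin_x,
                         dims = c(length(glin_rhs), nz))
  } else NULL

  # --- precompute constant Jacobian structure (D-blocks + globals) ---
  const_i <- integer(0); const_j <- integer(0); const_x <- numeric(0)
  # per-collocation-point bookkeeping for variable Jacobian entries
  pts <- list()
  for (i in seq_len(np)) {
    ph <- ph_info[[i]]
    msh <- ph$mesh; nx <- ph$nx
    D <- msh$grid$D; ord <- msh$order
    cnode <- 0L
    for (s in seq_len(msh$segments)) {
      hseg <- msh$bounds[s + 1] - msh$bounds[s]
      rows <- ((s - 1) * ord + 1):((s - 1) * ord + ord + 1)  # grid rows
      for (jn in seq_len(ord)) {
        cnode <- cnode + 1L
        defrows <- ph$defect_row0 + ((cnode - 1L) * nx) + seq_len(nx)
        # constant D part: defect_d gets sum_k D[jn,k] * X[rows[k], d]
        for (k in seq_len(ord + 1)) {
          const_i <- c(const_i, defrows)
          const_j <- c(const_j, ph$Xidx[rows[k], ])
          const_x <- c(const_x, rep(D[jn, k], nx))
        }
        pts[[length(pts) + 1]] <- list(
          phase = i, seg = s, hseg = hseg,
          xrow = rows[jn + 1L], cnode = cnode,
          defrows = defrows,
          w = msh$grid$weights[jn])
      }
    }
  }
  if (!is.null(Glin)) {
    gl <- Matrix::summary(Glin)
    const_i <- c(const_i, glin_row0 + gl$i)
    const_j <- c(const_j, gl$j)
    const_x <- c(const_x, gl$x)
  }

  cache <- new.env(parent = emptyenv())
  cache$z <- NULL

  eval_point <- function(z, pt, with_jac = FALSE) {
    ph <- ph_info[[pt$phase]]
    x <- z[ph$Xidx[pt$xrow, ]]
    u <- z[ph$Uidx[pt$cnode, ]]
    F <- ph$rates(x, u)
    out <- list(F = F)
    if (with_jac) out$A <- cs_rates_jac(ph$rates, x, u, ph$nx)
    out
  }

  con_fn <- function(z) {
    res <- numeric(m_total)
    for (i in seq_len(np)) {
      ph <- ph_info[[i]]
      msh <- ph$mesh; nx <- ph$nx; ord <- msh$order
      X <- matrix(z[ph$Xidx], msh$n_grid, nx)
      U <- matrix(z[ph$Uidx], msh$n_colloc, nu_ctrl)
      tf <- z[ph$tfidx]
      D <- msh$grid$D
      cnode <- 0L
      for (s in seq_len(msh$segments)) {
        hseg <- msh$bounds[s + 1] - msh$bounds[s]
        rows <- ((s - 1) * ord + 1):((s - 1) * ord + ord + 1)
        Xs <- X[rows, , drop = FALSE]
        DX <- D %*% Xs
        for (jn in seq_len(ord)) {
          cnode <- cnode + 1L
          F <- ph$rates(Xs[jn + 1L, ], U[cnode, ])
          r0 <- ph$defect_row0 + (cnode - 1L) * nx
          res[r0 + seq_len(nx)] <- DX[jn, ] - tf * hseg * F
        }
      }
    }
    for (lk in links) {
      res[lk$row0 + seq_len(lk$nr)] <- lk$fn(z[lk$vidx])
    }
    if (!is.null(Glin)) {
      res[glin_row0 + seq_along(glin_rhs)] <-
        as.numeric(Glin %*% z) - glin_rhs
    }
    res
  }

  # complex-step Jacobian of a link residual function
  link_jac <- function(fn, v, nr) {
    J <- matrix(0, nr, length(v)); h <- 1e-20
    for (j in seq_along(v)) {
      vc <- as.complex(v); vc[j] <- vc[j] + h * 1i
      J[, j] <- Im(fn(vc)) / h
    }
    J
  }

  jac_fn <- function(z) {
    ii <- const_i; jj <- const_j; xx <- const_x
    ptdata <- vector("list", length(pts))
    for (k in seq_along(pts)) {
      pt <- pts[[k]]
      ph <- ph_info[[pt$phase]]
      ev <- eval_point(z, pt, with_jac = TRUE)
      ptdata[[k]] <- ev
      tf <- z[ph$tfidx]
      sc <- -tf * pt$hseg
      cols <- c(ph$Xidx[pt$xrow, ], ph$Uidx[pt$cnode, ])
      A <- ev$A
      ii <- c(ii, rep(pt$defrows, length(cols)))
      jj <- c(jj, rep(cols, each = ph$nx))
      xx <- c(xx, as.numeric(sc * A))
      # d defect / d tf
      ii <- c(ii, pt$defrows)
      jj <- c(jj, rep(ph$tfidx, ph$nx))
      xx <- c(xx, -pt$hseg * ev$F)
    }
    lkdata <- vector("list", length(links))
    for (li in seq_along(links)) {
      lk <- links[[li]]
      Jl <- link_jac(lk$fn, z[lk$vidx], lk$nr)
      lkdata[[li]] <- Jl
      ii <- c(ii, rep(lk$row0 + seq_len(lk$nr), length(lk$vidx)))
      jj <- c(jj, rep(lk$vidx, each = lk$nr))
      xx <- c(xx, as.numeric(Jl))
    }
    cache$z <- z
    cache$pt <- ptdata
    cache$lk <- lkdata
    Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m_total, nz))
  }

  obj_fn <- function(z) {
    total <- 0
    for (ph in ph_info) {
      U <- matrix(z[ph$Uidx], ph$mesh$n_colloc, nu_ctrl)
      w <- point_weights(ph$mesh)
      total <- total + z[ph$tfidx] * sum(w * rowSums(U^2))
    }
    total
  }

  grad_fn <- function(z) {
    g <- numeric(nz)
    for (ph in ph_info) {
      U <- matrix(z[ph$Uidx], ph$mesh$n_colloc, nu_ctrl)
      w <- point_weights(ph$mesh)
      tf <- z[ph$tfidx]
      g[ph$Uidx] <- 2 * tf * as.numeric(w * U)
      g[ph$tfidx] <- sum(w * rowSums(U^2))
    }
    g
  }

  hess_fn <- function(z, lam) {
    if (is.null(cache$z) || !identical(cache$z, z)) invisible(jac_fn(z))
    hi <- integer(0); hj <- integer(0); hx <- numeric(0)
    for (k in seq_along(pts)) {
      pt <- pts[[k]]
      ph <- ph_info[[pt$phase]]
      nx <- ph$nx
      tf <- z[ph$tfidx]
      lamp <- lam[pt$defrows]
      x <- z[ph$Xidx[pt$xrow, ]]
      u <- z[ph$Uidx[pt$cnode, ]]
      xcols <- ph$Xidx[pt$xrow, ]; ucols <- ph$Uidx[pt$cnode, ]
      # objective block: u diagonal and (u, tf) cross
      wq <- pt$w * pt$hseg
      hi <- c(hi, ucols); hj <- c(hj, ucols); hx <- c(hx, rep(2 * tf * wq, nu_ctrl))
      hi <- c(hi, ucols, rep(ph$tfidx, nu_ctrl))
      hj <- c(hj, rep(ph$tfidx, nu_ctrl), ucols)
      hx <- c(hx, rep(2 * wq * u, 2))
      # dynamics curvature: + tf*h * H(lam' F) over the x block
      # (biomech components depend on x only; activation components
      # handled analytically below)
      A <- cache$pt[[k]]$A
      nbio <- if (ph$type == "propulsion") 2L else 6L
      arows <- (nbio + 1L):(nbio + 4L)
      Hx <- fd_cs_hess(function(xx) {
        Fb <- ph$rates(xx, as.complex(u))
        sum(lamp[seq_len(nbio)] * Fb[seq_len(nbio)]) +
          if (nx > nbio + 4L)
            sum(lamp[(nbio + 5L):nx] * Fb[(nbio + 5L):nx]) else 0
      }, x)
      sc <- tf * pt$hseg
      nzh <- which(abs(Hx) > 0, arr.ind = TRUE)
      if (nrow(nzh)) {
        hi <- c(hi, xcols[nzh[, 1]]); hj <- c(hj, xcols[nzh[, 2]])
        hx <- c(hx, sc * Hx[nzh])
      }
      # activation components: F_i = (u_i - a_i)(u_i/Ta + (1-u_i)/Td)
      rp <- 1 / muscles$Ta - 1 / muscles$Td
      acols_x <- if (ph$type == "propulsion") 3:6 else 7:10
      for (q in 1:4) {
        lq <- lamp[arows[q]]
        ai <- xcols[acols_x[q]]; ui <- ucols[q]
        hi <- c(hi, ai, ui, ui)
        hj <- c(hj, ui, ai, ui)
        hx <- c(hx, sc * lq * c(-rp, -rp, 2 * rp))
      }
      # (w, tf) cross terms: + h * A' lam
      Atl <- pt$hseg * as.numeric(crossprod(A, lamp))
      cols <- c(xcols, ucols)
      hi <- c(hi, cols, rep(ph$tfidx, length(cols)))
      hj <- c(hj, rep(ph$tfidx, length(cols)), cols)
      hx <- c(hx, rep(Atl, 2))
    }
    for (li in seq_along(links)) {
      lk <- links[[li]]
      laml <- lam[lk$row0 + seq_len(lk$nr)]
      if (max(abs(laml)) == 0) next
      v <- z[lk$vidx]
      Hl <- fd_cs_hess(function(vv) sum(laml * lk$fn(vv)), v)
      nzh <- which(abs(Hl) > 0, arr.ind = TRUE)
      if (nrow(nzh)) {
        hi <- c(hi, lk$vidx[nzh[, 1]]); hj <- c(hj, lk$vidx[nzh[, 2]])
        hx <- c(hx, -Hl[nzh])
      }
    }
    Matrix::sparseMatrix(i = hi, j = hj, x = hx, dims = c(nz, nz))
  }

  structure(list(
    nz = nz, m = m_total, lb = lb, ub = ub,
    phases = ph_info, links = links, scenario = scenario,
    assisted = assisted, params = params, muscles = muscles,
    controller = controller,
    obj = obj_fn, grad = grad_fn, con = con_fn, jac = jac_fn,
    hess = hess_fn), class = "paw_nlp")
}

# quadrature weight of every collocation point of a phase (segment
# fraction times Radau weight), in collocation order
point_weights <- function(msh) {
  h <- diff(msh$bounds)
  as.numeric(vapply(seq_len(msh$segments),
                    function(s) h[s] * msh$grid$weights,
                    numeric(msh$order)))
}

# symmetric Hessian of a scalar complex-step-differentiable function by
# forward differencing its complex-step gradient
fd_cs_hess <- function(f, x) {
  n <- length(x)
  hcs <- 1e-20
  csg <- function(xx) {
    g <- numeric(n)
    for (j in seq_len(n)) {
      xc <- as.complex(xx); xc[j] <- xc[j] + hcs * 1i
      g[j] <- Im(f(xc)) / hcs
    }
    g
  }
  g0 <- csg(x)
  H <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-5 * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    H[, j] <- (csg(xp) - g0) / h
  }
  (H + t(H)) / 2
}
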