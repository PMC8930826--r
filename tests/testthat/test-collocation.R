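test_that("Radau grid is exact for polynomials", {
  expect_error(radau_grid(0), "order")
  g1 <- radau_grid(1)
  expect_equal(g1$nodes, 1)
  for (n in c(2, 5, 10, 20)) {
    g <- radau_grid(n)
    expect_equal(g$nodes[n], 1)
    expect_true(all(g$nodes > 0))
    expect_true(all(g$weights > 0))
    expect_equal(sum(g$weights), 1, tolerance = 1e-13)
    supp <- c(0, g$nodes)
    for (k in 0:n) {
      d <- g$D %*% supp^k
      expect_equal(as.numeric(d),
                   if (k == 0) rep(0, n) else k * g$nodes^(k - 1),
                   tolerance = 1e-11)
    }
    for (k in 0:(2 * n - 2)) {
      expect_equal(sum(g$weights * g$nodes^k), 1 / (k + 1),
                   tolerance = 1e-12)
    }
  }
})

# minimal fake solutions for the effort quadratures
fake_solution <- function(ufun, tf = 1, order = 20, assisted = FALSE,
                          xi_fun = NULL) {
  msh <- pawsim:::build_phase_mesh(1, order)
  cf <- pawsim:::colloc_fracs(msh)
  U <- t(vapply(cf * tf, ufun, numeric(4)))
  nx <- if (assisted) 8L else 6L
  X <- matrix(0, msh$n_grid, nx)
  if (assisted && !is.null(xi_fun)) {
    gf <- pawsim:::grid_fracs(msh)
    X[, 8] <- vapply(gf * tf, xi_fun, numeric(1))
  }
  ctrl <- if (assisted) {
    list(pi = list(Kp = 0, Ki = 1), imp = impedance_params())
  } else NULL
  structure(list(
    phases = list(list(type = "propulsion", tf = tf, X = X, U = U,
                       mesh = msh)),
    nlp = list(assisted = assisted, controller = ctrl,
               params = default_parameters())),
    class = "paw_solution")
}

test_that("user effort is the quadrature of squared excitations", {
  expect_equal(effort_user(fake_solution(function(t) rep(0.5, 4))), 1)
  expect_equal(effort_user(fake_solution(function(t) rep(0, 4))), 0)
  # polynomial excitation u_se(t) = t on [0, 1]: integral 1/3
  expect_equal(effort_user(fake_solution(function(t) c(t, 0, 0, 0))),
               1 / 3, tolerance = 1e-12)
})

test_that("motor effort is the quadrature of squared motor torque", {
  expect_equal(effort_motor(fake_solution(function(t) rep(0.3, 4))), 0)
  # constant 10 N m over 2 s through Ki = 1, xi = 10
  s_const <- fake_solution(function(t) rep(0, 4), tf = 2, assisted = TRUE,
                           xi_fun = function(t) 10)
  expect_equal(effort_motor(s_const), 200, tolerance = 1e-10)
  # sinusoidal torque: integral of sin^2(2 pi t) over [0, 1] is 1/2
  s_sin <- fake_solution(function(t) rep(0, 4), tf = 1, assisted = TRUE,
                         xi_fun = function(t) sin(2 * pi * t))
  expect_equal(effort_motor(s_sin), 0.5, tolerance = 1e-10)
})

test_that("collocation plus interior point solves a toy problem exactly", {
  # double integrator, minimum effort rest-to-rest transfer on [0, 1]:
  # analytic optimum u(t) = 6 - 12 t with objective 12
  ord <- 5; nseg <- 2
  g <- radau_grid(ord)
  bounds <- seq(0, 1, length.out = nseg + 1)
  nXg <- nseg * ord + 1
  # variables: x (nXg), v (nXg), u at collocation nodes (nseg * ord)
  nu <- nseg * ord
  nz <- 2 * nXg + nu
  ix <- 1:nXg; iv <- nXg + (1:nXg); iu <- 2 * nXg + (1:nu)
  con <- function(z) {
    x <- z[ix]; v <- z[iv]; u <- z[iu]
    res <- numeric(2 * nu + 4)
    r <- 0
    for (s in 1:nseg) {
      rows <- ((s - 1) * ord + 1):((s - 1) * ord + ord + 1)
      h <- bounds[s + 1] - bounds[s]
      un <- u[((s - 1) * ord + 1):(s * ord)]
      res[r + 1:ord] <- g$D %*% x[rows] - h * v[rows][-1]
      res[r + ord + 1:ord] <- g$D %*% v[rows] - h * un
      r <- r + 2 * ord
    }
    res[r + 1:4] <- c(x[1], v[1], x[nXg] - 1, v[nXg])
    res
  }
  jac <- function(z) {
    m <- 2 * nu + 4
    J <- matrix(0, m, nz)
    r <- 0
    for (s in 1:nseg) {
      rows <- ((s - 1) * ord + 1):((s - 1) * ord + ord + 1)
      h <- bounds[s + 1] - bounds[s]
      for (j in 1:ord) {
        J[r + j, ix[rows]] <- g$D[j, ]
        J[r + j, iv[rows[j + 1]]] <- -h
        J[r + ord + j, iv[rows]] <- g$D[j, ]
        J[r + ord + j, iu[(s - 1) * ord + j]] <- -h
      }
      r <- r + 2 * ord
    }
    J[r + 1, ix[1]] <- 1; J[r + 2, iv[1]] <- 1
    J[r + 3, ix[nXg]] <- 1; J[r + 4, iv[nXg]] <- 1
    Matrix::Matrix(J, sparse = TRUE)
  }
  w_all <- rep(diff(bounds), each = ord) * rep(g$weights, nseg)
  obj <- function(z) sum(w_all * z[iu]^2)
  grad <- function(z) {
    gv <- numeric(nz); gv[iu] <- 2 * w_all * z[iu]; gv
  }
  hess <- function(z, lam) {
    Matrix::Diagonal(nz, c(rep(0, 2 * nXg), 2 * w_all))
  }
  res <- pawsim:::solve_nlp(rep(0.1, nz), rep(-Inf, nz), rep(Inf, nz),
                            obj, grad, con, jac, hess,
                            list(tol = 1e-8, max_iter = 100))
  expect_identical(res$status, "success")
  expect_equal(res$objective, 12, tolerance = 1e-6)
  # control matches 6 - 12 t at the collocation nodes
  tnodes <- as.numeric(vapply(1:nseg, function(s)
    bounds[s] + diff(bounds)[s] * g$nodes, numeric(ord)))
  expect_equal(res$z[iu], 6 - 12 * tnodes, tolerance = 1e-5)
})

test_that("transcription bookkeeping matches the study problem sizes", {
  p <- default_parameters(); mus <- default_muscles()
  # steady state: two free phase durations; startup: five
  for (cond in c("level-steady", "level-startup")) {
    sc <- build_scenario(cond, "off")
    nlp <- pawsim:::transcribe(
      lapply(sc$phase_types, function(t) list(type = t)),
      scenario_mesh(sc, "default"), p, mus, NULL,
      list(kind = sc$kind, v_avg = 0.9, displacement = sc$displacement))
    expect_length(nlp$phases, length(sc$phase_types))
    tf_idx <- vapply(nlp$phases, function(ph) ph$tfidx, numeric(1))
    expect_length(unique(tf_idx), if (sc$kind == "steady") 2L else 5L)
  }
  # the reported fine mesh: 100 startup propulsion collocation points
  # (10 polynomials of order 10), 144 recovery points (12 of order 12),
  # and 5 x 20 per steady-state phase
  scs <- build_scenario("level-startup", "off")
  fine <- scenario_mesh(scs, "fine")
  expect_equal(fine[[1]]$segments * fine[[1]]$order, 100)
  expect_equal(fine[[2]]$segments * fine[[2]]$order, 144)
  scd <- build_scenario("level-steady", "off")
  fined <- scenario_mesh(scd, "fine")
  expect_equal(vapply(fined, function(m) m$segments * m$order, numeric(1)),
               c(100, 100))
  # assisted problems append the two controller states
  imp <- impedance_params()
  ctrl <- list(imp = imp, pi = design_pi(imp, p$wheel_radius))
  nlp_a <- pawsim:::transcribe(
    lapply(scd$phase_types, function(t) list(type = t)),
    scenario_mesh(scd, "default"), p, mus, ctrl,
    list(kind = "steady", v_avg = 0.9))
  expect_equal(nlp_a$phases[[1]]$nx, 8L)
  expect_equal(nlp_a$phases[[2]]$nx, 12L)
})
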