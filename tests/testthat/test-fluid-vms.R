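props11 <- fluid_properties(1, 1)

test_that("stabilization coefficients reproduce the closed-form cases", {
  G <- diag(2)
  pr <- fluid_properties(1, 0)
  # transient term only: tau_m = dt / sqrt(CT)
  tau <- compute_tau(c(0, 0), G, s = 1, dt = 0.01, pr, stab_params(CT = 4))
  expect_equal(tau$tau_m, 0.005, tolerance = 1e-14)
  # s = 100 divides tau_m by 10 when only the transient term survives
  tau100 <- compute_tau(c(0, 0), G, s = 100, dt = 0.01, pr, stab_params(CT = 4))
  expect_equal(tau100$tau_m, 5e-4, tolerance = 1e-14)
  # on a uniform grid: tau_c = h^2 / (8 tau_m)
  h <- 1 / 16
  Gh <- (4 / h^2) * diag(2)
  th <- compute_tau(c(0, 0), Gh, s = 1, dt = 0.01, pr, stab_params())
  expect_equal(th$tau_c, h^2 / (8 * th$tau_m), tolerance = 1e-12)
})

test_that("tau_m decreases in s, |v| and viscosity; tau_c tau_m trG = 1", {
  set.seed(11)
  for (k in 1:20) {
    A <- matrix(rnorm(4), 2)
    G <- crossprod(A) + 0.5 * diag(2)
    v <- rnorm(2)
    pr <- fluid_properties(runif(1, 0.5, 2), runif(1, 0.01, 1))
    st <- stab_params()
    t0 <- compute_tau(v, G, 1, 0.02, pr, st)
    expect_lt(compute_tau(v, G, 10, 0.02, pr, st)$tau_m, t0$tau_m)
    expect_lt(compute_tau(2 * v, G, 1, 0.02, pr, st)$tau_m, t0$tau_m)
    pr2 <- fluid_properties(pr$rho, pr$mu * 3)
    expect_lt(compute_tau(v, G, 1, 0.02, pr2, st)$tau_m, t0$tau_m)
    expect_equal(t0$tau_c * t0$tau_m * sum(diag(G)), 1, tolerance = 1e-13)
  }
})

test_that("s-field marks the interface band through the pressure basis nodes", {
  m <- unit_square(16)
  expect_equal(build_s_field(m, NULL), rep(1, nrow(m$nodes)))
  # a solid node coincident with fluid node 25
  stab <- stab_params(s_max = 1000, band_halfwidth = 2)
  s <- build_s_field(m, m$nodes[25, , drop = FALSE], stab)
  expect_equal(s[25], 1000)
  # nodes beyond the band stay at 1, the band respects its radius
  d <- sqrt(colSums((t(m$nodes) - m$nodes[25, ])^2))
  expect_true(all(s[d > 2 / 16 + 1e-12] == 1))
  expect_true(all(s[d <= 2 / 16] == 1000))
})

test_that("quiescent and hydrostatic states give vanishing residuals", {
  m <- unit_square(8)
  n <- nrow(m$nodes)
  zero <- matrix(0, n, 2)
  r <- assemble_fluid(m, zero, zero, rep(0, n), rep(1, n), props11,
                      stab_params(), 0.01, jacobian = FALSE)
  expect_equal(max(abs(c(r$Rm, r$Rc))), 0)
  # gravity balanced by a linear (exactly representable) pressure
  g <- 9.81; rho <- 2
  pr <- fluid_properties(rho, 0.3, body_force = c(0, -g))
  p_hydro <- rho * g * (1 - m$nodes[, 2])
  fn <- matrix(rep(c(0, -g), each = n), n, 2)
  r <- assemble_fluid(m, zero, zero, p_hydro, rep(1, n), pr, stab_params(),
                      0.01, fnod = fn, jacobian = FALSE)
  # boundary momentum rows carry the (Dirichlet-eliminated) wall reaction;
  # interior momentum and all mass rows balance pointwise
  bnod <- boundary_nodes(m, 1:4)
  interior <- setdiff(seq_len(n), bnod)
  idofs <- as.vector(outer(1:2, 2 * (interior - 1L), `+`))
  expect_lt(max(abs(r$Rm[idofs])), 1e-11)
  expect_lt(max(abs(r$Rc)), 1e-11)
})

test_that("the assembled Jacobian matches a finite-difference directional derivative", {
  set.seed(4)
  m <- unit_square(4)
  n <- nrow(m$nodes)
  pr <- fluid_properties(1.2, 0.05)
  stab <- stab_params()
  dt <- 0.01
  chain <- list(cv = 0.35 * dt, ca = 5 / 6, cp = 0.35 * dt)
  Vb <- matrix(rnorm(2 * n), n, 2); Pb <- rnorm(n)
  s <- rep(1, n); s[sample(n, 4)] <- 1000
  fn <- matrix(rnorm(2 * n), n, 2)
  evalr <- function(Vdv, Pdv) {
    Vd <- matrix(Vdv, ncol = 2, byrow = TRUE)
    r <- assemble_fluid(m, Vb + chain$cv * Vd, chain$ca * Vd, Pb + chain$cp * Pdv,
                        s, pr, stab, dt, chain, fnod = fn, jacobian = FALSE)
    c(r$Rm, r$Rc)
  }
  Vd0 <- rnorm(2 * n); Pd0 <- rnorm(n)
  out <- assemble_fluid(m, Vb + chain$cv * matrix(Vd0, ncol = 2, byrow = TRUE),
                        chain$ca * matrix(Vd0, ncol = 2, byrow = TRUE),
                        Pb + chain$cp * Pd0, s, pr, stab, dt, chain,
                        fnod = fn, jacobian = TRUE)
  del <- rnorm(3 * n); del <- del / sqrt(sum(del^2))
  eps <- 1e-6
  fd <- (evalr(Vd0 + eps * del[1:(2 * n)], Pd0 + eps * del[(2 * n + 1):(3 * n)]) -
         evalr(Vd0 - eps * del[1:(2 * n)], Pd0 - eps * del[(2 * n + 1):(3 * n)])) /
        (2 * eps)
  Jd <- as.vector(out$J %*% del)
  expect_lt(sqrt(sum((fd - Jd)^2)) / sqrt(sum(Jd^2)), 1e-5)
})

test_that("inflow profiles evaluate to their printed values", {
  expect_equal(ramp_pressure(0.05), 1.5e5)
  expect_equal(ramp_pressure(0.1), 3e5)
  expect_equal(ramp_pressure(2.0), 3e5)
  # continuity at the ramp junction
  expect_equal(ramp_pressure(0.1 - 1e-12), 3e5, tolerance = 1e-10)
  expect_equal(leaflet_profile(0.25, 1), 15.0)
  expect_equal(leaflet_profile(0.4, 0), 0)
  expect_equal(leaflet_profile(0.4, 2), 0)
  expect_equal(parabolic_pulsatile(0, 0.5), 0)
  expect_equal(parabolic_pulsatile(0.5, 0), 0)
  expect_equal(plug_flow(0.3, Q = function(t) 10 * t, A = 6), 0.5)
})

test_that("global mass balance holds for enclosed stirred flow", {
  # all-Dirichlet velocity boundary: integral of div v_h stays at roundoff
  m <- unit_square(12)
  lid <- function(t, X) 16 * X[, 1]^2 * (1 - X[, 1])^2
  case <- fsi_case(m, fluid_properties(1, 0.05),
                   vbc = c(wall_bcs(), list(list(tag = "top", comp = 1, value = lid))))
  cfg <- solver_config(dt = 0.02)
  st <- init_state(case)
  for (k in 1:5) st <- solve_time_step(case, st, cfg)$state
  V <- matrix(st$V, ncol = 2, byrow = TRUE)
  # integral of div v over each element via quadrature
  q <- quadrature_rule("quad4", 2)
  acc <- 0
  for (e in seq_len(nrow(m$elem))) {
    conn <- m$elem[e, ]
    X <- m$nodes[conn, ]
    for (iq in seq_along(q$w)) {
      dsh <- elem_shape("quad4", q$points[iq, ])
      J <- crossprod(X, dsh$dN)
      dNdx <- dsh$dN %*% solve(J)
      acc <- acc + q$w[iq] * det(J) * sum(diag(crossprod(V[conn, ], dNdx)))
    }
  }
  expect_lt(abs(acc), 1e-8 * max(abs(V)) * 4)
})

test_that("manufactured divergence-free solution converges at optimal order", {
  # steady trigonometric field with matching body force; march to the
  # discrete steady state and compare spatial errors on two uniform meshes
  rho <- 1; mu <- 1; nu <- mu / rho
  v_ex <- function(x) c(sin(pi*x[1])*cos(pi*x[2]), -cos(pi*x[1])*sin(pi*x[2]))
  p_ex <- function(x) sin(pi*x[1])*sin(pi*x[2]) - 4/pi^2
  f_ex <- function(t, x) {
    v <- v_ex(x)
    G <- rbind(c(pi*cos(pi*x[1])*cos(pi*x[2]), -pi*sin(pi*x[1])*sin(pi*x[2])),
               c(pi*sin(pi*x[1])*sin(pi*x[2]), -pi*cos(pi*x[1])*cos(pi*x[2])))
    as.vector(G %*% v) +
      c(pi*cos(pi*x[1])*sin(pi*x[2]), pi*sin(pi*x[1])*cos(pi*x[2]))/rho -
      nu*(-2*pi^2*v)
  }
  errs <- t(sapply(c(8, 16), function(N) {
    m <- unit_square(N)
    bc1 <- lapply(c("left","right","bottom","top"), function(tg)
      list(tag = tg, comp = 1, value = function(t, X) apply(X,1,function(x) v_ex(x)[1])))
    bc2 <- lapply(c("left","right","bottom","top"), function(tg)
      list(tag = tg, comp = 2, value = function(t, X) apply(X,1,function(x) v_ex(x)[2])))
    case <- fsi_case(m, fluid_properties(rho, mu, body_force = f_ex),
                     vbc = c(bc1, bc2))
    cfg <- solver_config(dt = 0.25, rtol = 1e-6, max_newton = 20, rho_inf = 0)
    st <- init_state(case)
    for (k in 1:30) {
      prev <- st$V
      st <- solve_time_step(case, st, cfg)$state
      if (max(abs(st$V - prev)) < 1e-9 * max(abs(st$V))) break
    }
    V <- matrix(st$V, ncol = 2, byrow = TRUE)
    ph <- st$P - ifsi:::.integrate_nodal(m, field = st$P)
    pe <- function(x) p_ex(x) - ifsi:::.integrate_nodal(m, fn = p_ex)
    c(ev = l2_error(V, v_ex, m), ep = l2_error(ph, pe, m))
  }))
  rate_v <- log2(errs[1, "ev"] / errs[2, "ev"])
  rate_p <- log2(errs[1, "ep"] / errs[2, "ep"])
  expect_gt(rate_v, 1.8)    # velocity: second order (fit slack on two meshes)
  expect_gt(rate_p, 1.5)    # pressure: at least the interface-free 1.5
})
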