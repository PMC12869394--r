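# shared builders for the test suite; everything is generated in code

wall_bcs <- function(value = 0)
  list(list(tag = "left", value = value), list(tag = "right", value = value),
       list(tag = "bottom", value = value), list(tag = "top", value = value))

unit_square <- function(N) build_cartesian_grid(list(c(0, 1), c(0, 1)), c(N, N))

# small immersed-annulus case (the equilibrium benchmark, coarse)
mini_annulus_case <- function(N = 16, s_max = 1) {
  m <- unit_square(N)
  M <- as.integer(2 * N / 16)
  ann <- build_annulus_solid(0.25, 0.0625, 112L * M, M, center = c(0.5, 0.5))
  fsi_case(m, fluid_properties(1, 1), stab = stab_params(s_max = s_max),
           solid = solid_state(ann, material_fiber(1), rho0 = 1),
           vbc = wall_bcs())
}

# divergence-free trigonometric manufactured solution with matching body
# force for the steady Navier-Stokes balance
manufactured <- function(rho, mu) {
  nu <- mu / rho
  v_ex <- function(x) c(sin(pi * x[1]) * cos(pi * x[2]),
                        -cos(pi * x[1]) * sin(pi * x[2]))
  gradv_ex <- function(x) rbind(
    c(pi * cos(pi * x[1]) * cos(pi * x[2]), -pi * sin(pi * x[1]) * sin(pi * x[2])),
    c(pi * sin(pi * x[1]) * sin(pi * x[2]), -pi * cos(pi * x[1]) * cos(pi * x[2])))
  p_ex <- function(x) sin(pi * x[1]) * sin(pi * x[2]) - 4 / pi^2
  f_ex <- function(t, x) {
    v <- v_ex(x); G <- gradv_ex(x)
    conv <- as.vector(G %*% v)
    gp <- c(pi * cos(pi * x[1]) * sin(pi * x[2]),
            pi * sin(pi * x[1]) * cos(pi * x[2]))
    lap <- -2 * pi^2 * v
    conv + gp / rho - nu * lap
  }
  list(v = v_ex, gradv = gradv_ex, p = p_ex, f = f_ex)
}

# drive a fluid-only case to its discrete steady state
steady_solve <- function(case, cfg, nsteps = 40, tol = 1e-9) {
  st <- init_state(case)
  for (k in seq_len(nsteps)) {
    prev <- st$V
    st <- solve_time_step(case, st, cfg)$state
    if (max(abs(st$V - prev)) < tol * max(1, max(abs(st$V)))) break
  }
  st
}

expect_rel <- function(x, y, tol) expect_lt(abs(x - y) / max(abs(y), 1e-300), tol)

`%||%` <- function(a, b) if (is.null(a)) b else a
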