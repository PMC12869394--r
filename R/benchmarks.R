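## Verification benchmark drivers: the immersed annulus in static equilibrium
## (analytic pressure, convergence rates), the idealized open and closed
## valves, the oscillating flexible leaflet, and the free-falling sphere with
## wall-corrected Stokes terminal velocity.

#' Analytic equilibrium solution of the immersed annulus
#'
#' A fiber-reinforced annulus (inner radius R, thickness w, circumferential
#' fiber modulus mu_s) immersed in a closed box of quiescent fluid. The fiber
#' prestress sigma = mu_s e_theta (x) e_theta implies the radial equilibrium
#' dp/dr = -mu_s / r across the wall, so the velocity vanishes and the
#' pressure is: p_out outside, p_out + mu_s log((R+w)/r) within the annulus,
#' and p_out + mu_s log(1 + w/R) in the hole.
#'
#' @param x evaluation point.
#' @param R,w,mu_s annulus geometry and fiber modulus.
#' @param center annulus center.
#' @param p_out outer pressure level (additive constant; the convergence
#'   study removes means before comparing).
#' @return list with \code{v} (zero vector) and \code{p}.
#' @export
annulus_analytic <- function(x, R = 0.25, w = 0.0625, mu_s = 1,
                             center = c(0.5, 0.5), p_out = 0) {
  r <- sqrt(sum((x[1:2] - center)^2))
  p <- if (r >= R + w) p_out
       else if (r <= R) p_out + mu_s * log((R + w) / R)
       else p_out + mu_s * log((R + w) / r)
  list(v = c(0, 0), p = p)
}

.integrate_nodal <- function(mesh, field = NULL, fn = NULL, quad_order = 3L) {
  q <- quadrature_rule(mesh$elem_type, quad_order)
  shp <- lapply(seq_along(q$w), function(iq) elem_shape(mesh$elem_type, q$points[iq, ]))
  acc <- 0
  for (e in seq_len(nrow(mesh$elem))) {
    conn <- mesh$elem[e, ]
    X <- mesh$nodes[conn, , drop = FALSE]
    for (iq in seq_along(q$w)) {
      d <- shp[[iq]]
      detJ <- det(crossprod(X, d$dN))
      val <- if (is.null(fn)) sum(field[conn] * d$N)
             else fn(as.vector(crossprod(X, d$N)))
      acc <- acc + q$w[iq] * detJ * val
    }
  }
  acc
}

#' Least-squares convergence rates from an error table
#'
#' Slope of log(error) against log(h), fitted over all rows (at least 3
#' meshes for a meaningful fit).
#' @export
convergence_rates <- function(h, errors) {
  if (is.null(dim(errors))) errors <- matrix(errors, ncol = 1)
  apply(errors, 2, function(e) unname(coef(lm(log(e) ~ log(h)))[2]))
}

#' Assemble the annulus equilibrium case
#' @keywords internal
.annulus_case <- function(N, s_max = 1, mu_s = 1, R = 0.25, w = 0.0625) {
  m <- build_cartesian_grid(list(c(0, 1), c(0, 1)), c(N, N))
  M <- as.integer(2 * N / 16)
  ann <- build_annulus_solid(R, w, 112L * M, M, center = c(0.5, 0.5))
  sol <- solid_state(ann, material_fiber(mu_s), rho0 = 1)
  fsi_case(m, fluid_properties(1, 1), stab = stab_params(s_max = s_max),
           solid = sol,
           vbc = list(list(tag = "left", value = 0), list(tag = "right", value = 0),
                      list(tag = "top", value = 0), list(tag = "bottom", value = 0)))
}

#' Immersed-annulus convergence study
#'
#' For each N: a uniform N x N fluid grid on the unit square (rho_f = mu_f =
#' 1), a (112 M) x M annulus solid with M = 2N/16 (solid elements twice as
#' fine as the fluid), 10 implicit steps of dt = 1e-3 to equilibrium, then
#' L2 velocity, L2 pressure (mean-removed) and H1-seminorm velocity errors
#' against the analytic solution, with least-squares log-log rates.
#'
#' The interface s-scaling stays at 1 here: this equilibrium study exercises
#' the base VMS discretization (the scaling targets thin-structure pressure
#' jumps and leaves a small steady interface current that masks the
#' velocity convergence of this smooth benchmark).
#'
#' @param N_list ascending fluid resolutions, each divisible by 16.
#' @param steps,dt time stepping of the equilibration.
#' @param s_max interface scaling for the study.
#' @param verbose print per-mesh errors.
#' @return list with \code{table} (h and errors), \code{rates} (named:
#'   l2_velocity, l2_pressure, h1_velocity).
#' @export
run_annulus_convergence <- function(N_list = c(16, 32, 64), steps = 10,
                                    dt = 1e-3, s_max = 1, verbose = FALSE) {
  stopifnot(!is.unsorted(N_list), all(N_list %% 16 == 0))
  rows <- lapply(N_list, function(N) {
    case <- .annulus_case(N, s_max = s_max)
    cfg <- solver_config(dt = dt)
    st <- init_state(case)
    for (k in seq_len(steps)) st <- solve_time_step(case, st, cfg)$state
    m <- case$fluid
    pex <- function(x) annulus_analytic(x)$p
    mh <- .integrate_nodal(m, field = st$P)
    me <- .integrate_nodal(m, fn = pex)
    Vmat <- .vec2mat(st$V, 2L)
    row <- c(h = 1 / N,
             l2_velocity = l2_error(Vmat, function(x) c(0, 0), m),
             l2_pressure = l2_error(st$P - mh, function(x) pex(x) - me, m),
             h1_velocity = h1_seminorm_error(Vmat, function(x) matrix(0, 2, 2), m))
    if (verbose)
      message(sprintf("N=%d: L2v=%.3e L2p=%.3e H1v=%.3e",
                      N, row[2], row[3], row[4]))
    row
  })
  tab <- do.call(rbind, rows)
  rates <- convergence_rates(tab[, "h"], tab[, c("l2_velocity", "l2_pressure",
                                                 "h1_velocity")])
  list(table = as.data.frame(tab), rates = rates)
}

#' Closed-valve benchmark
#'
#' A 4 x 1 cm channel (CGS units) with a single elastic beam of thickness
#' 0.0212 cm spanning the full height at x = 2, clamped at the bottom wall;
#' the inlet pressure ramps to 3e5 dyne/cm^2 over 0.1 s and is then held.
#' The steady state is hydrostatic: zero velocity, with the pressure jump
#' carried across the beam (upstream 3e5, downstream 0). Run until the
#' velocity norm plateaus (or \code{t_end}).
#'
#' @param mesh_level 1, 2, 3 selecting fluid meshes 128x32, 256x64, 512x128
#'   with solid meshes 5x64, 5x128, 5x256.
#' @param s_max interface stabilization scaling.
#' @param t_end maximum simulated time.
#' @param dt time-step size.
#' @param steady_window,steady_tol plateau detection: stop when the velocity
#'   norm changes by less than \code{steady_tol} times its running peak over
#'   \code{steady_window} consecutive steps.
#' @return list with the time \code{series} (max speed, probe pressures, tip
#'   displacement), steady-state \code{p_upstream}, \code{p_downstream},
#'   \code{max_speed}, \code{peak_speed} (pre-closure), and mesh info.
#' @export
run_closed_valve <- function(mesh_level = 1, s_max = 1000, t_end = 3,
                             dt = 1e-3, rho_inf = 0, steady_window = 50L,
                             steady_tol = 1e-6, verbose = FALSE) {
  fx <- c(128L, 256L, 512L)[mesh_level] ; fy <- fx / 4L
  sy <- c(64L, 128L, 256L)[mesh_level]
  m <- build_cartesian_grid(list(c(0, 4), c(0, 1)), c(fx, fy))
  beam <- build_beam_solid(c(2 - 0.0212 / 2, 0), 0.0212, 1.0, 5L, sy)
  sol <- solid_state(beam, material_neo_hookean(5.6e7, 0.4), rho0 = 100,
                     clamped = "clamped")
  case <- fsi_case(m, fluid_properties(100, 10),
                   stab = stab_params(s_max = s_max), solid = sol,
                   vbc = list(list(tag = "bottom", value = 0),
                              list(tag = "top", value = 0)),
                   traction = list(list(tag = "left",
                                        value = bc_pressure(ramp_pressure))))
  # rho_inf = 0 damps the post-ramp structural ringing fastest; the steady
  # state itself does not depend on the damping parameter
  cfg <- solver_config(dt = dt, rho_inf = rho_inf, factor_every_pass = FALSE)
  st <- init_state(case)
  probes <- rbind(c(1, 0.5), c(3, 0.5))
  nmax <- as.integer(round(t_end / dt))
  ts <- matrix(NA_real_, nmax, 5,
               dimnames = list(NULL, c("t", "max_speed", "p_up", "p_down", "tip_x")))
  peak <- 0
  env_prev <- Inf
  k <- 0L
  for (k in seq_len(nmax)) {
    st <- solve_time_step(case, st, cfg)$state
    sp <- sqrt(rowSums(.vec2mat(st$V, 2)^2))
    pp <- interp_field(case$locator, st$P, probes)
    tip <- max(.vec2mat(st$u, 2)[, 1])
    ts[k, ] <- c(st$t, max(sp), pp[1], pp[2], tip)
    peak <- max(peak, ts[k, "max_speed"])
    if (verbose && k %% 50 == 0)
      message(sprintf("t=%.3f maxV=%.3e p_up=%.4g p_down=%.4g tip=%.3f",
                      st$t, ts[k, "max_speed"], pp[1], pp[2], tip))
    # plateau detection: the upstream pressure mean over successive windows
    # stops changing and the velocity-amplitude envelope is no longer growing
    if (k %% steady_window == 0L && k > 2L * steady_window && st$t > 0.3) {
      w1 <- (k - 2L * steady_window + 1L):(k - steady_window)
      w2 <- (k - steady_window + 1L):k
      dp <- abs(mean(ts[w2, "p_up"]) - mean(ts[w1, "p_up"]))
      env1 <- max(ts[w1, "max_speed"]); env2 <- max(ts[w2, "max_speed"])
      if (dp < 5e-3 * abs(mean(ts[w2, "p_up"])) && env2 < 1.2 * env1) break
      env_prev <- env2
    }
  }
  ts <- ts[seq_len(k), , drop = FALSE]
  tail_idx <- max(1L, k - 2L * steady_window):k
  list(series = as.data.frame(ts),
       p_upstream = mean(ts[tail_idx, "p_up"]),
       p_downstream = mean(ts[tail_idx, "p_down"]),
       max_speed = max(ts[tail_idx, "max_speed"]), peak_speed = peak,
       steady = k < nmax, mesh = c(fx, fy), dt = dt, s_max = s_max)
}

#' Open-valve benchmark (two separated cantilever leaflets)
#'
#' An 8.0 x 1.61 cm channel (CGS) with two leaflets of thickness 0.0212 cm
#' and height 0.7 cm at x = 2, one clamped to each wall and purposefully
#' separated to avoid contact; pulsatile parabolic inflow at Re = 110,
#' compressible Neo-Hookean leaflets (E = 5.6e7 dyne/cm^2, nu = 0.4).
#' Outputs the top-leaflet tip displacement time series.
#'
#' @param fluid_counts fluid mesh element counts \code{c(nx, ny)}.
#' @param solid_counts per-leaflet solid mesh counts \code{c(nx, ny)}.
#' @param t_end,dt simulated time and step.
#' @param V0,period inflow amplitude and period (reconstruction; defaults
#'   realize peak-velocity Re = 110).
#' @export
run_open_valve <- function(fluid_counts = c(128, 32), solid_counts = c(4, 100),
                           t_end = 1, dt = 1e-3,
                           V0 = 110 * 10 / (100 * 1.61), period = 1,
                           s_max = 1000, verbose = FALSE) {
  H <- 1.61
  m <- build_cartesian_grid(list(c(0, 8), c(0, H)), c(fluid_counts[1], fluid_counts[2]))
  w <- 0.0212
  bot <- build_beam_solid(c(2 - w / 2, 0), w, 0.7, solid_counts[1], solid_counts[2])
  top <- build_beam_solid(c(2 - w / 2, 0), w, 0.7, solid_counts[1], solid_counts[2])
  top$nodes[, 2] <- H - top$nodes[, 2]  # mirrored leaflet hanging from the top
  top$elem <- top$elem[, c(4, 3, 2, 1)] # restore orientation after mirroring
  leaf <- merge_meshes(bot, top, prefix = c("bottom", "top"))
  clamped <- c(boundary_nodes(bot, "clamped"),
               boundary_nodes(top, "clamped") + nrow(bot$nodes))
  sol <- solid_state(leaf, material_neo_hookean(5.6e7, 0.4), rho0 = 100,
                     clamped = clamped)
  inflow <- function(t, X) parabolic_pulsatile(t, X[, 2], V0 = V0, H = H,
                                               period = period)
  case <- fsi_case(m, fluid_properties(100, 10),
                   stab = stab_params(s_max = s_max), solid = sol,
                   vbc = list(list(tag = "bottom", value = 0),
                              list(tag = "top", value = 0),
                              list(tag = "left", comp = 1, value = inflow),
                              list(tag = "left", comp = 2, value = 0)))
  # top leaflet tip: free end (minimum y of the mirrored strip), mid-thickness
  tip_node <- nrow(bot$nodes) +
    which.min(top$nodes[, 2] + abs(top$nodes[, 1] - 2))
  .run_tip_series(case, sol, tip_node, t_end, dt, verbose)
}

.run_tip_series <- function(case, sol, tip_node, t_end, dt, verbose) {
  cfg <- solver_config(dt = dt)
  st <- init_state(case)
  nmax <- as.integer(round(t_end / dt))
  ts <- matrix(NA_real_, nmax, 3, dimnames = list(NULL, c("t", "tip_x", "tip_y")))
  d <- case$dim
  for (k in seq_len(nmax)) {
    st <- solve_time_step(case, st, cfg)$state
    U <- .vec2mat(st$u, d)
    ts[k, ] <- c(st$t, U[tip_node, 1], U[tip_node, 2])
    if (verbose && k %% 100 == 0)
      message(sprintf("t=%.3f tip=(%.4f, %.4f)", st$t, ts[k, 2], ts[k, 3]))
  }
  list(series = as.data.frame(ts), tip_node = tip_node, state = st)
}

#' Oscillating flexible leaflet benchmark
#'
#' A 4 x 1 m channel (SI) with a leaflet (w = 0.0212 m, h = 0.8 m) mounted
#' perpendicular to the stream at x = 2; pulsatile inflow
#' \eqn{v = 15 y (2-y) \sin(2\pi t)} drives large periodic deformations.
#' Nearly-incompressible Neo-Hookean leaflet (C0 = 1e7 Pa, kappa_s = C0/10),
#' solid density equal to the fluid's (100 kg/m^3).
#'
#' @param fluid_counts,solid_counts mesh element counts.
#' @param t_end,dt simulated time and step size.
#' @export
run_oscillating_leaflet <- function(fluid_counts = c(96, 24),
                                    solid_counts = c(2, 40),
                                    t_end = 3, dt = 1e-3, s_max = 1000,
                                    verbose = FALSE) {
  m <- build_cartesian_grid(list(c(0, 4), c(0, 1)), fluid_counts)
  w <- 0.0212
  leaf <- build_beam_solid(c(2 - w / 2, 0), w, 0.8, solid_counts[1], solid_counts[2])
  sol <- solid_state(leaf, material_uncoupled_neo_hookean(1e7, 1e6), rho0 = 100,
                     clamped = "clamped")
  inflow <- function(t, X) leaflet_profile(t, X[, 2])
  case <- fsi_case(m, fluid_properties(100, 10),
                   stab = stab_params(s_max = s_max), solid = sol,
                   vbc = list(list(tag = "bottom", value = 0),
                              list(tag = "top", value = 0),
                              list(tag = "left", comp = 1, value = inflow),
                              list(tag = "left", comp = 2, value = 0)))
  tip_node <- which.max(leaf$nodes[, 2] - abs(leaf$nodes[, 1] - 2))
  .run_tip_series(case, sol, tip_node, t_end, dt, verbose)
}

#' Stokes terminal velocity with cylindrical-wall correction
#'
#' Unbounded-domain creeping-flow terminal speed
#' \eqn{v_t = (2 g / 9 \mu_f) a^2 (\rho_s - \rho_f)}, the axial-cylinder wall
#' correction factor (Bohlin series, valid for a/A < 0.6)
#' \eqn{K = [1 - 2.10443 x + 2.08877 x^3 - 0.94813 x^5 - 1.372 x^6]^{-1}}
#' with x = a/A, and the corrected speed \eqn{v_t^c = v_t / K} (K > 1: rigid
#' walls add viscous dissipation and slow the sphere).
#'
#' @param a sphere radius; \code{A} cylinder radius.
#' @param rho_s,rho_f solid and fluid densities.
#' @param mu_f fluid dynamic viscosity.
#' @param g gravitational acceleration magnitude.
#' @return list with \code{v_t}, \code{K}, \code{v_t_corrected}.
#' @export
stokes_terminal_velocity <- function(a, A, rho_s, rho_f, mu_f, g = 981) {
  if (a / A >= 0.6)
    stop("wall correction invalid: requires a/A < 0.6")
  v_t <- 2 * g / (9 * mu_f) * a^2 * (rho_s - rho_f)
  x <- a / A
  K <- 1 / (1 - 2.10443 * x + 2.08877 * x^3 - 0.94813 * x^5 - 1.372 * x^6)
  list(v_t = v_t, K = K, v_t_corrected = v_t / K)
}

#' Free-falling sphere benchmark
#'
#' A sphere (radius 0.25 cm, initial density 1.5 g/cm^3, stiff
#' nearly-incompressible Neo-Hookean) released at (0, 0, 2.5) in a
#' fluid-filled cylinder (radius 2 cm, height 4 cm, rho_f = 1 g/cm^3,
#' mu_f = 10 P) open at the top, falling under gravity (0, 0, -981) cm/s^2
#' toward its wall-corrected terminal velocity.
#'
#' @param n,nz cylinder tet-mesh resolution (see
#'   \code{\link{build_cylinder_tets}}); \code{n_sphere} solid resolution.
#' @param t_end,dt simulated time and step.
#' @return list with the time \code{series} of the mean solid vertical
#'   velocity, the \code{plateau} value (mean over the trailing 20% of
#'   steps), the analytic \code{reference}, and the percent difference.
#' @export
run_falling_sphere <- function(n = 6L, nz = 15L, n_sphere = 4L,
                               t_end = 0.03, dt = 5e-4, s_max = 1000,
                               C0 = 33550, verbose = FALSE) {
  m <- build_cylinder_tets(2, 4, n = n, nz = nz)
  sph <- build_sphere_hexes(0.25, center = c(0, 0, 2.5), n = n_sphere)
  sol <- solid_state(sph, material_uncoupled_neo_hookean(C0, 10 * C0),
                     rho0 = 1.5)
  g <- c(0, 0, -981)
  case <- fsi_case(m, fluid_properties(1, 10, body_force = g),
                   stab = stab_params(s_max = s_max), solid = sol,
                   vbc = list(list(tag = "side", value = 0),
                              list(tag = "bottom", value = 0)),
                   solid_body_force = g)
  # creeping flow: the Jacobian varies slowly, so one factorization serves
  # several steps (the Newton convergence check always uses the true residual)
  cfg <- solver_config(dt = dt, factor_every_pass = FALSE, refactor_every = 5L)
  st <- init_state(case)
  nmax <- as.integer(round(t_end / dt))
  ts <- matrix(NA_real_, nmax, 2, dimnames = list(NULL, c("t", "w_mean")))
  for (k in seq_len(nmax)) {
    st <- solve_time_step(case, st, cfg)$state
    ts[k, ] <- c(st$t, mean(.vec2mat(st$ud, 3)[, 3]))
    if (verbose && k %% 10 == 0)
      message(sprintf("t=%.4f w_mean=%.4f", st$t, ts[k, 2]))
  }
  ref <- stokes_terminal_velocity(0.25, 2, 1.5, 1, 10)
  plateau <- mean(ts[ceiling(0.8 * nmax):nmax, "w_mean"])
  list(series = as.data.frame(ts), plateau = plateau, reference = ref,
       percent_difference = 100 * abs(abs(plateau) - ref$v_t_corrected) /
         ref$v_t_corrected,
       mesh = c(fluid_elems = nrow(m$elem), solid_elems = nrow(sph$elem)))
}
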