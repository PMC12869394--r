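## Generalized-alpha time integration, the predictor-multicorrector Newton
## loop, and the reduced monolithic system: the solid acceleration unknowns
## are eliminated through the constraint matrix, so the linear system has the
## size of a fluid-only problem (velocity + pressure DOFs).

#' Generalized-alpha coefficients from the spectral radius at infinity
#'
#' First-order-system family: \eqn{\alpha_m = (3-\rho_\infty)/(2(1+\rho_\infty))},
#' \eqn{\alpha_f = 1/(1+\rho_\infty)}, \eqn{\gamma = 1/2 + \alpha_m - \alpha_f};
#' second-order accurate and unconditionally stable for \eqn{0 \le \rho_\infty \le 1}.
#' @export
genalpha_coefficients <- function(rho_inf) {
  if (rho_inf < 0 || rho_inf > 1)
    stop("rho_inf must lie in [0, 1]")
  alpha_m <- 0.5 * (3 - rho_inf) / (1 + rho_inf)
  alpha_f <- 1 / (1 + rho_inf)
  list(alpha_m = alpha_m, alpha_f = alpha_f,
       gamma = 0.5 + alpha_m - alpha_f, rho_inf = rho_inf)
}

#' Solver configuration
#'
#' @param dt time-step size.
#' @param max_newton maximum corrector passes per step.
#' @param rtol relative residual reduction for convergence.
#' @param atol absolute residual tolerance.
#' @param linear_solver \code{"direct"} (sparse LU) or \code{"gmres+block"}
#'   (GMRES with an upper-triangular block preconditioner; pressure Schur
#'   complement approximated by the pressure stabilization block).
#' @param rho_inf generalized-alpha spectral radius at infinity.
#' @param lin_tol relative tolerance of the iterative linear solver.
#' @param direct_backend \code{"matrix"} (default; CSparse LU via the Matrix
#'   package, whose unconditional partial pivoting keeps fill predictable on
#'   these stabilized saddle-point systems) or \code{"eigen"} (supernodal
#'   SparseLU; faster on some well-scaled systems but its threshold pivoting
#'   can blow up fill on others).
#' @param factor_every_pass refactor the system matrix at every corrector
#'   pass (exact Newton). With FALSE the factorization from the first pass of
#'   each step is reused (quasi-Newton): each later pass costs only an
#'   assembly and a backsolve, at the price of possibly a few more passes --
#'   worthwhile for 3D runs where the factorization dominates.
#' @param refactor_every with \code{factor_every_pass = FALSE}, refactor only
#'   every this many steps (default 1): slowly varying systems (creeping
#'   flow) tolerate a stale factorization for several steps because the
#'   convergence check always uses the true residual. If a step fails to
#'   contract under a stale factor, it refactors once and retries before
#'   raising a step failure.
#' @param constraint_rebuilds number of leading corrector passes that rebuild
#'   the constraint matrix from the moving solid position; afterwards it is
#'   frozen for the remainder of the step (the position increments of later
#'   passes are below the constraint's resolution, and freezing restores the
#'   quadratic convergence of Newton, whose Jacobian does not carry the
#'   derivative of the interpolation operator with respect to position).
#' @export
solver_config <- function(dt, max_newton = 10L, rtol = 1e-4, atol = 1e-10,
                          linear_solver = c("direct", "gmres+block"),
                          rho_inf = 0.5, lin_tol = 1e-10,
                          direct_backend = NULL,
                          factor_every_pass = TRUE,
                          refactor_every = 1L,
                          constraint_rebuilds = 2L) {
  stopifnot(dt > 0, rtol > 0, atol > 0, max_newton >= 1)
  list(dt = dt, max_newton = as.integer(max_newton), rtol = rtol, atol = atol,
       linear_solver = match.arg(linear_solver), rho_inf = rho_inf,
       lin_tol = lin_tol, direct_backend = direct_backend,
       factor_every_pass = isTRUE(factor_every_pass),
       refactor_every = as.integer(refactor_every),
       constraint_rebuilds = as.integer(constraint_rebuilds))
}

#' Traction boundary condition from a prescribed pressure
#'
#' Returns \code{h = -p(t) n}: the Neumann traction of a pressure applied on
#' a fluid boundary (n the outward normal).
#' @export
bc_pressure <- function(p_fn) {
  force(p_fn)
  function(t, x, n) -p_fn(t) * n
}

#' FSI case container
#'
#' Bundles the background fluid mesh, fluid properties, stabilization, an
#' optional immersed solid, and boundary conditions.
#'
#' @param fluid_mesh background mesh (role "fluid").
#' @param props fluid properties.
#' @param stab stabilization parameters.
#' @param solid optional \code{\link{solid_state}}.
#' @param vbc list of strong velocity Dirichlet entries: each
#'   \code{list(tag=|nodes=, comp=, value=)} with \code{value} a number or
#'   \code{function(t, X)} over the entry's node coordinates. Later entries
#'   override earlier ones on shared DOFs.
#' @param traction list of Neumann entries \code{list(tag=, value=)} with
#'   \code{value = function(t, x, n)} returning the traction vector (see
#'   \code{\link{bc_pressure}}); untagged boundary is traction-free.
#' @param solid_body_force constant acceleration on the solid (e.g. gravity).
#' @param pin_pressure NULL (auto: pin one pressure DOF iff no traction BC),
#'   FALSE, or a node index to pin at zero.
#' @export
fsi_case <- function(fluid_mesh, props, stab = stab_params(), solid = NULL,
                     vbc = list(), traction = list(),
                     solid_body_force = NULL, pin_pressure = NULL) {
  d <- fluid_mesh$dim
  n <- nrow(fluid_mesh$nodes)
  # normalize Dirichlet entries
  entries <- lapply(vbc, function(e) {
    nodes <- if (!is.null(e$nodes)) as.integer(e$nodes)
             else boundary_nodes(fluid_mesh, e$tag)
    comp <- if (is.null(e$comp)) seq_len(d) else as.integer(e$comp)
    list(nodes = nodes, comp = comp, value = e$value)
  })
  dir_dofs <- integer(0)
  for (e in entries)
    for (i in e$comp) dir_dofs <- c(dir_dofs, d * (e$nodes - 1L) + i)
  dir_dofs <- sort(unique(dir_dofs))
  if (is.null(pin_pressure))
    pin_pressure <- if (length(traction) == 0L) 1L else FALSE
  pin_node <- if (isFALSE(pin_pressure)) integer(0) else as.integer(pin_pressure)

  freev <- setdiff(seq_len(d * n), dir_dofs)
  freep <- setdiff(seq_len(n), pin_node)
  structure(list(
    fluid = fluid_mesh, props = props, stab = stab, solid = solid,
    vbc = entries, traction = traction,
    solid_body_force = solid_body_force,
    dir_dofs = dir_dofs, pin_node = pin_node,
    freev = freev, freep = freep,
    free = c(freev, d * n + freep),
    locator = point_locator(fluid_mesh),
    h = mesh_size(fluid_mesh),
    nv = d * n, np = n, dim = d,
    clamped_dofs = if (!is.null(solid) && length(solid$clamped))
      as.vector(outer(seq_len(d), d * (solid$clamped - 1L), `+`)) else integer(0)
  ), class = "ifsi_case")
}

#' @export
print.ifsi_case <- function(x, ...) {
  cat(sprintf("ifsi case: %d fluid DOFs (%d velocity + %d pressure)%s\n",
              x$nv + x$np, x$nv, x$np,
              if (is.null(x$solid)) ", no immersed solid"
              else sprintf(", immersed solid with %d nodes",
                           nrow(x$solid$mesh$nodes))))
  invisible(x)
}

#' Initial (zero) state for a case
#' @export
init_state <- function(case, t0 = 0) {
  ns <- if (is.null(case$solid)) 0L else nrow(case$solid$mesh$nodes) * case$dim
  st <- list(t = t0,
             V = numeric(case$nv), Vd = numeric(case$nv),
             P = numeric(case$np), Pd = numeric(case$np),
             u = numeric(ns), ud = numeric(ns), udd = numeric(ns))
  # start from consistent Dirichlet values at t0
  dv <- .dirichlet_values(case, t0)
  st$V[dv$dofs] <- dv$values
  st
}

.vec2mat <- function(v, d) matrix(v, ncol = d, byrow = TRUE)
.mat2vec <- function(m) as.vector(t(m))

.dirichlet_values <- function(case, t) {
  d <- case$dim
  vals <- numeric(case$nv)
  has <- logical(case$nv)
  for (e in case$vbc) {
    X <- case$fluid$nodes[e$nodes, , drop = FALSE]
    for (i in e$comp) {
      dofs <- d * (e$nodes - 1L) + i
      v <- if (is.function(e$value)) e$value(t, X) else e$value
      vals[dofs] <- v
      has[dofs] <- TRUE
    }
  }
  list(dofs = which(has), values = vals[has])
}

.assemble_traction <- function(case, t) {
  d <- case$dim
  R <- numeric(case$nv)
  if (length(case$traction) == 0L) return(R)
  mesh <- case$fluid
  for (e in case$traction) {
    tag <- if (is.character(e$tag)) mesh$boundary$tag_names[[e$tag]] else e$tag
    fac <- mesh$boundary$facets[mesh$boundary$tag == tag, , drop = FALSE]
    for (f in seq_len(nrow(fac))) {
      conn <- fac[f, ]
      X <- mesh$nodes[conn, , drop = FALSE]
      if (d == 2L) {
        tau <- X[2, ] - X[1, ]
        len <- sqrt(sum(tau^2))
        nrm <- c(tau[2], -tau[1]) / len
        gp <- c(-(1 / sqrt(3)), 1 / sqrt(3))
        for (q in gp) {
          N <- c((1 - q) / 2, (1 + q) / 2)
          x <- as.vector(crossprod(X, N))
          h <- e$value(t, x, nrm)
          w <- len / 2
          for (a in 1:2)
            R[d * (conn[a] - 1L) + seq_len(d)] <-
              R[d * (conn[a] - 1L) + seq_len(d)] + w * N[a] * h
        }
      } else {
        qr2 <- quadrature_rule("quad4", 2L)
        tri <- nrow(X) == 3L
        qr <- if (tri) quadrature_rule("tri3", 2L) else qr2
        et <- if (tri) "tri3" else "quad4"
        for (iq in seq_along(qr$w)) {
          sh <- elem_shape(et, qr$points[iq, ])
          Jt <- crossprod(X, sh$dN)   # 3 x 2
          nr <- c(Jt[2, 1] * Jt[3, 2] - Jt[3, 1] * Jt[2, 2],
                  Jt[3, 1] * Jt[1, 2] - Jt[1, 1] * Jt[3, 2],
                  Jt[1, 1] * Jt[2, 2] - Jt[2, 1] * Jt[1, 2])
          area <- sqrt(sum(nr^2))
          nrm <- nr / area
          x <- as.vector(crossprod(X, sh$N))
          h <- e$value(t, x, nrm)
          for (a in seq_len(nrow(X)))
            R[d * (conn[a] - 1L) + seq_len(d)] <-
              R[d * (conn[a] - 1L) + seq_len(d)] + qr$w[iq] * area * sh$N[a] * h
        }
      }
    }
  }
  R
}

## Evaluate the stacked residual (and block Jacobian) at given step-(n+1)
## rate unknowns, with the constraint matrix and s-field frozen. The solid
## kinematics follow the rates through the generalized-alpha update chain and
## the nodal constraint, so the returned Jacobian is the consistent
## derivative of the returned residual.
.eval_system <- function(case, state, dt, co, Vd1, Pd1, Cl, sfield,
                         want_jac = TRUE, anchor = NULL) {
  d <- case$dim
  g <- co$gamma; af <- co$alpha_f; am <- co$alpha_m
  chain <- list(cv = af * g * dt, ca = am, cp = af * g * dt)
  V1 <- state$V + dt * state$Vd + g * dt * (Vd1 - state$Vd)
  P1 <- state$P + dt * state$Pd + g * dt * (Pd1 - state$Pd)
  Vaf <- state$V + af * (V1 - state$V)
  Vdam <- state$Vd + am * (Vd1 - state$Vd)
  Paf <- state$P + af * (P1 - state$P)
  taf <- state$t + af * dt

  sol <- NULL
  if (!is.null(case$solid)) {
    # velocity slaved to the fluid through the constraint; acceleration
    # advanced incrementally (delta Udd = C^T delta Vd from the anchor, the
    # state at the last constraint rebuild) so a change of the interpolation
    # operator between steps is never amplified by 1/dt
    if (is.null(anchor))
      anchor <- list(udd = ((g - 1) / g) * state$udd, Vd = Vd1)
    ud1 <- interpolate_to_solid(Cl, V1)
    ud1[case$clamped_dofs] <- 0
    udd1 <- anchor$udd + interpolate_to_solid(Cl, Vd1 - anchor$Vd)
    udd1[case$clamped_dofs] <- 0
    u1 <- state$u + dt * state$ud + g * dt * (ud1 - state$ud)
    uaf <- state$u + af * (u1 - state$u)
    udaf <- state$ud + af * (ud1 - state$ud)
    uddam <- state$udd + am * (udd1 - state$udd)
    sol <- list(u = u1, ud = ud1, udd = udd1, uaf = uaf)
  }

  fl <- assemble_fluid(case$fluid, .vec2mat(Vaf, d), .vec2mat(Vdam, d), Paf,
                       sfield, case$props, case$stab, dt, chain,
                       jacobian = want_jac, t = taf)
  Rm <- fl$Rm - .assemble_traction(case, taf)
  Rc <- fl$Rc
  A <- if (want_jac) fl$J else NULL

  if (!is.null(case$solid)) {
    schain <- list(fu = af * g^2 * dt^2, fv = af * g * dt, fa = am)
    sa <- assemble_immersed_solid(case$solid, .vec2mat(uaf, d),
                                  .vec2mat(udaf, d), .vec2mat(uddam, d),
                                  case$props, schain,
                                  body_force = case$solid_body_force,
                                  jacobian = want_jac)
    Rs <- sa$Rs
    Rs[case$clamped_dofs] <- 0
    Rm <- Rm + spread_to_fluid(Cl, Rs)
    if (want_jac) {
      Ks <- sa$K
      if (length(case$clamped_dofs)) {
        Ks[case$clamped_dofs, ] <- 0
        Ks[, case$clamped_dofs] <- 0
      }
      CKsCt <- Cl$C %*% Ks %*% Matrix::t(Cl$C)
      nv <- case$nv; np <- case$np
      Cpad <- rbind(cbind(CKsCt, Matrix::Matrix(0, nv, np, sparse = TRUE)),
                    Matrix::Matrix(0, np, nv + np, sparse = TRUE))
      A <- A + Cpad
    }
    sol$Rs <- Rs
  }
  list(r = c(Rm, Rc), A = A, sol = sol, V1 = V1, P1 = P1)
}

.gmres <- function(A, b, Mfun, tol = 1e-10, maxit = 300L) {
  n <- length(b)
  x <- numeric(n)
  bn <- sqrt(sum(b^2))
  if (bn == 0) return(x)
  r <- b
  V <- matrix(0, n, maxit + 1L)
  H <- matrix(0, maxit + 1L, maxit)
  cs <- sn <- numeric(maxit)
  gvec <- numeric(maxit + 1L)
  z <- Mfun(r)
  beta <- sqrt(sum(z^2))
  V[, 1] <- z / beta
  gvec[1] <- beta
  k <- 0L
  for (j in seq_len(maxit)) {
    w <- Mfun(as.vector(A %*% V[, j]))
    for (i in seq_len(j)) {
      H[i, j] <- sum(w * V[, i])
      w <- w - H[i, j] * V[, i]
    }
    H[j + 1L, j] <- sqrt(sum(w^2))
    if (H[j + 1L, j] > 0) V[, j + 1L] <- w / H[j + 1L, j]
    for (i in seq_len(max(0L, j - 1L))) {
      tmp <- cs[i] * H[i, j] + sn[i] * H[i + 1L, j]
      H[i + 1L, j] <- -sn[i] * H[i, j] + cs[i] * H[i + 1L, j]
      H[i, j] <- tmp
    }
    den <- sqrt(H[j, j]^2 + H[j + 1L, j]^2)
    cs[j] <- H[j, j] / den; sn[j] <- H[j + 1L, j] / den
    H[j, j] <- den; H[j + 1L, j] <- 0
    gvec[j + 1L] <- -sn[j] * gvec[j]
    gvec[j] <- cs[j] * gvec[j]
    k <- j
    if (abs(gvec[j + 1L]) < tol * beta) break
  }
  y <- backsolve(H[seq_len(k), seq_len(k), drop = FALSE], gvec[seq_len(k)])
  as.vector(V[, seq_len(k), drop = FALSE] %*% y)
}

.ifsi_solver_env <- new.env(parent = emptyenv())
.ifsi_solver_env$handle <- -1L
.ifsi_solver_env$fact <- NULL
.ifsi_solver_env$age <- 0L      # steps since the last factorization
.ifsi_solver_env$dim <- NULL    # size of the cached factorization

.solve_linear <- function(case, cfg, A, rhs, refactor = TRUE) {
  if (cfg$linear_solver == "direct") {
    backend <- cfg$direct_backend %||% "matrix"
    A <- as(A, "CsparseMatrix")
    # a cached factorization from a different system (other size) is useless
    if (!refactor && !identical(.ifsi_solver_env$dim, nrow(A))) refactor <- TRUE
    if (backend == "eigen") {
      if (refactor || .ifsi_solver_env$handle < 0L) {
        .ifsi_solver_env$handle <- cpp_splu_factor(A, .ifsi_solver_env$handle)
        .ifsi_solver_env$dim <- nrow(A)
      }
      return(as.vector(cpp_splu_solve(.ifsi_solver_env$handle, rhs)))
    }
    if (refactor || is.null(.ifsi_solver_env$fact)) {
      .ifsi_solver_env$fact <- Matrix::lu(A)
      .ifsi_solver_env$dim <- nrow(A)
    }
    return(as.vector(Matrix::solve(.ifsi_solver_env$fact, rhs)))
  }
  # upper-triangular block preconditioner: velocity block and pressure
  # stabilization (Schur surrogate) factored once per Newton iteration
  nvf <- length(case$freev)
  iv <- seq_len(nvf); ip <- (nvf + 1L):length(rhs)
  Avv <- A[iv, iv]; Avp <- A[iv, ip, drop = FALSE]; Spp <- A[ip, ip]
  Fv <- Matrix::lu(Avv); Fp <- Matrix::lu(Spp)
  Mfun <- function(r) {
    zp <- as.vector(Matrix::solve(Fp, r[ip]))
    zv <- as.vector(Matrix::solve(Fv, r[iv] - as.vector(Avp %*% zp)))
    c(zv, zp)
  }
  .gmres(A, rhs, Mfun, tol = cfg$lin_tol)
}

#' Advance one time step
#'
#' Predictor-multicorrector generalized-alpha step: same-rate predictor,
#' then Newton corrections of the reduced monolithic system (fluid momentum
#' with the spread solid residual, fluid mass) for the velocity/pressure rate
#' increments; solid acceleration increments follow through the transpose of
#' the constraint matrix. The s-field and the constraint matrix are rebuilt
#' from the current solid position at every corrector pass.
#'
#' @param case \code{\link{fsi_case}}.
#' @param state current converged state (\code{\link{init_state}}).
#' @param cfg \code{\link{solver_config}}.
#' @return list with \code{state} (at t + dt) and \code{report} (iteration
#'   counts and residual norms).
#' @export
solve_time_step <- function(case, state, cfg) {
  dt <- cfg$dt
  d <- case$dim
  co <- genalpha_coefficients(cfg$rho_inf)
  g <- co$gamma
  t1 <- state$t + dt

  Vd1 <- ((g - 1) / g) * state$Vd
  Pd1 <- ((g - 1) / g) * state$Pd
  # strong Dirichlet at t_{n+1} through the update formula
  dv <- .dirichlet_values(case, t1)
  Vd1[dv$dofs] <- (dv$values - state$V[dv$dofs] -
                     (1 - g) * dt * state$Vd[dv$dofs]) / (g * dt)
  if (length(case$pin_node)) Pd1[case$pin_node] <- 0

  # current-iterate solid position for the constraint rebuilds
  uaf_est <- if (!is.null(case$solid)) state$u + co$alpha_f * dt * state$ud
             else NULL

  norms <- numeric(0)
  nrm0 <- NA_real_
  Cl <- NULL; sfield <- rep(1, case$np)
  ev <- NULL
  converged <- FALSE
  # the interface band (s-field) is rebuilt once per step from the predictor
  # solid position; the constraint matrix follows the solid through the
  # corrector passes. A fixed band may be supplied through cfg$frozen_sfield
  # (steady-state seeking with an essentially static interface).
  if (!is.null(case$solid))
    sfield <- if (!is.null(cfg$frozen_sfield)) cfg$frozen_sfield
              else build_s_field(case$fluid,
                                 case$solid$mesh$nodes + .vec2mat(uaf_est, d),
                                 case$stab, case$h)
  nreb <- if (is.null(cfg$constraint_rebuilds)) 2L else cfg$constraint_rebuilds
  g <- co$gamma
  anchor <- if (!is.null(case$solid))
    list(udd = ((g - 1) / g) * state$udd, Vd = Vd1) else NULL
  for (it in seq_len(cfg$max_newton + 1L)) {
    if (!is.null(case$solid) && (it <= nreb || is.null(Cl))) {
      xs <- case$solid$mesh$nodes + .vec2mat(uaf_est, d)
      Cl <- build_constraint_matrix(case$locator, xs)
      # re-anchor the incremental acceleration update to the new operator
      if (!is.null(ev) && !is.null(ev$sol))
        anchor <- list(udd = ev$sol$udd, Vd = Vd1)
    }
    ev <- .eval_system(case, state, dt, co, Vd1, Pd1, Cl, sfield,
                       want_jac = TRUE, anchor = anchor)
    if (!is.null(ev$sol)) uaf_est <- state$u + co$alpha_f * (ev$sol$u - state$u)
    r <- ev$r[case$free]
    nrm <- sqrt(sum(r^2))
    norms <- c(norms, nrm)
    if (it == 1L) nrm0 <- nrm
    if (nrm <= cfg$atol || nrm <= cfg$rtol * nrm0) { converged <- TRUE; break }
    if (it > cfg$max_newton) break
    refac <- if (isTRUE(cfg$factor_every_pass)) TRUE
             else if (it == 1L) {
               period <- max(1L, cfg$refactor_every %||% 1L)
               .ifsi_solver_env$age >= period - 1L
             } else FALSE
    # stale-factor safeguard: if passes accumulate without contraction,
    # force a fresh factorization before giving up
    if (!refac && it >= cfg$max_newton - 1L) refac <- TRUE
    if (refac) .ifsi_solver_env$age <- -1L   # bumped to 0 below on step end
    dx <- .solve_linear(case, cfg, ev$A[case$free, case$free], -r,
                        refactor = refac)
    nvf <- length(case$freev)
    Vd1[case$freev] <- Vd1[case$freev] + dx[seq_len(nvf)]
    Pd1[case$freep] <- Pd1[case$freep] + dx[(nvf + 1L):length(dx)]
  }
  .ifsi_solver_env$age <- .ifsi_solver_env$age + 1L
  report <- list(t = t1, iterations = length(norms), residuals = norms,
                 converged = converged, system_size = case$nv + case$np)
  if (!converged)
    stop(errorCondition(
      sprintf("Newton failed to converge at t = %g (residual %.3e after %d passes)",
              t1, norms[length(norms)], length(norms)),
      class = c("ifsi_step_failure", "error", "condition"), report = report))

  st <- list(t = t1, V = ev$V1, Vd = Vd1, P = ev$P1, Pd = Pd1,
             u = if (is.null(ev$sol)) state$u else ev$sol$u,
             ud = if (is.null(ev$sol)) state$ud else ev$sol$ud,
             udd = if (is.null(ev$sol)) state$udd else ev$sol$udd,
             sfield = sfield, Cl = Cl)
  list(state = st, report = report)
}

#' Run a transient simulation
#'
#' Loops \code{\link{solve_time_step}} to \code{t_end}, optionally sampling a
#' user callback each step (for time series) and checkpointing at a cadence.
#' A run restarted from a checkpoint reproduces the uninterrupted trajectory
#' (bitwise, with the direct linear solver).
#'
#' @param case,cfg case and solver configuration.
#' @param t_end final time; the number of steps is \code{round(t_end/dt)}.
#' @param state0 initial state (default \code{init_state(case)}).
#' @param callback optional \code{function(state, report)} whose results are
#'   collected into the returned \code{series} list.
#' @param checkpoint_path optional RDS path written every
#'   \code{checkpoint_every} steps; pass its contents as \code{state0} to
#'   resume.
#' @param max_steps optional cap on the number of steps taken.
#' @param verbose print per-step Newton counts.
#' @return list with final \code{state}, per-step \code{reports}, and
#'   \code{series} (callback results).
#' @export
run_transient <- function(case, t_end, cfg, state0 = NULL, callback = NULL,
                          checkpoint_path = NULL, checkpoint_every = 50L,
                          max_steps = NULL, verbose = FALSE) {
  state <- if (is.null(state0)) init_state(case) else state0
  nsteps <- max(0L, as.integer(round((t_end - state$t) / cfg$dt)))
  if (!is.null(max_steps)) nsteps <- min(nsteps, as.integer(max_steps))
  reports <- vector("list", nsteps)
  series <- if (is.null(callback)) NULL else vector("list", nsteps)
  for (k in seq_len(nsteps)) {
    out <- solve_time_step(case, state, cfg)
    state <- out$state
    reports[[k]] <- out$report
    if (!is.null(callback)) series[[k]] <- callback(state, out$report)
    if (verbose)
      cat(sprintf("step %d t=%.5g newton=%d res=%.3e\n", k, state$t,
                  out$report$iterations,
                  out$report$residuals[length(out$report$residuals)]))
    if (!is.null(checkpoint_path) && (k %% checkpoint_every == 0L || k == nsteps))
      saveRDS(state, checkpoint_path)
  }
  list(state = state, reports = reports, series = series)
}
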