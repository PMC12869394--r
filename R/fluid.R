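## VMS-stabilized incompressible Navier-Stokes: properties, stabilization
## coefficients, the interface s-field, assembly wrappers, inflow profiles.

#' Fluid properties
#'
#' @param rho fluid density (mass/volume, > 0).
#' @param mu dynamic viscosity (pressure * time, >= 0).
#' @param body_force constant acceleration vector, or a function
#'   \code{f(t, x)} returning one (evaluated at the fluid nodes).
#' @export
fluid_properties <- function(rho, mu, body_force = NULL) {
  stopifnot(rho > 0, mu >= 0)
  list(rho = rho, mu = mu, body_force = body_force)
}

#' Stabilization parameters
#'
#' \code{CI} is the inverse-estimate constant (36 for linear bases), \code{CT}
#' the time-stepping constant (4). \code{s_max} is the interface scaling
#' applied to the transient term of the momentum stabilization coefficient in
#' an O(h) band around the immersed solid; \code{band_halfwidth} is the band
#' half-width in multiples of the local fluid mesh size.
#' @export
stab_params <- function(CI = 36, CT = 4, s_max = 1000, band_halfwidth = 2) {
  stopifnot(CI > 0, CT > 0, s_max >= 1, band_halfwidth > 0)
  list(CI = CI, CT = CT, s_max = s_max, band_halfwidth = band_halfwidth)
}

#' VMS stabilization coefficients
#'
#' \eqn{\tau_m = [s C_T/\Delta t^2 + v \cdot G v + C_I (\mu/\rho)^2 G:G]^{-1/2}}
#' and \eqn{\tau_c = (\tau_m \mathrm{tr} G)^{-1}}. The interface factor
#' \eqn{s \ge 1} multiplies the transient term, so \eqn{s \gg 1} locally
#' reduces \eqn{\tau_m} (and by reciprocity boosts \eqn{\tau_c}).
#'
#' @param v element velocity (length dim).
#' @param G element metric tensor.
#' @param s interface scaling (>= 1).
#' @param dt time-step size.
#' @param props from \code{\link{fluid_properties}}.
#' @param stab from \code{\link{stab_params}}.
#' @return list with \code{tau_m} (time) and \code{tau_c} (length^2/time).
#' @export
compute_tau <- function(v, G, s, dt, props, stab = stab_params()) {
  stopifnot(dt > 0, s >= 1)
  nu <- props$mu / props$rho
  tau_m <- 1 / sqrt(s * stab$CT / dt^2 + sum(v * (G %*% v)) +
                    stab$CI * nu^2 * sum(G * G))
  list(tau_m = tau_m, tau_c = 1 / (tau_m * sum(diag(G))))
}

#' Interface s-field at the fluid nodes
#'
#' Fluid nodes within \code{band_halfwidth * h} of any solid node receive
#' \code{s_max}; all others 1. The nodal values are interpolated through the
#' pressure (equal-order linear) basis during assembly, giving the smooth
#' transition; the field is recomputed whenever the solid moves.
#'
#' @param fluid_mesh background mesh.
#' @param solid_positions current solid node coordinates (matrix), or NULL.
#' @param stab stabilization parameters.
#' @param h local fluid mesh size; default the mean element diameter-equivalent
#'   \code{(volume/nel)^(1/dim)}.
#' @export
build_s_field <- function(fluid_mesh, solid_positions, stab = stab_params(),
                          h = NULL) {
  n <- nrow(fluid_mesh$nodes)
  s <- rep(1, n)
  if (is.null(solid_positions) || nrow(solid_positions) == 0L) return(s)
  if (is.null(h)) h <- mesh_size(fluid_mesh)
  near <- cpp_mark_near(fluid_mesh$nodes, solid_positions,
                        stab$band_halfwidth * h)
  s[near] <- stab$s_max
  s
}

#' Characteristic element size of a mesh
#' @export
mesh_size <- function(mesh) {
  (mesh_volume(mesh, 2L) / nrow(mesh$elem))^(1 / mesh$dim)
}

.nodal_body_force <- function(props, mesh, t) {
  n <- nrow(mesh$nodes); d <- mesh$dim
  bf <- props$body_force
  if (is.null(bf)) return(matrix(0, n, d))
  if (is.function(bf)) {
    out <- t(apply(mesh$nodes, 1, function(x) bf(t, x)))
    if (ncol(out) != d) out <- matrix(out, n, d)
    return(out)
  }
  matrix(rep(as.numeric(bf), each = n), n, d)
}

#' Assemble the VMS fluid residual and Jacobian blocks
#'
#' Returns the momentum and mass residuals of the stabilized Navier-Stokes
#' weak form (Galerkin terms with the full material derivative, plus
#' SUPG/PSPG, grad-div, convective cross and Reynolds fine-scale terms with
#' quasi-static subscales), and optionally the consistent Jacobian with
#' respect to the rate unknowns through the caller-supplied generalized-alpha
#' chain factors.
#'
#' @param mesh fluid mesh.
#' @param v,vdot nodal velocity at the alpha_f level and rate at the alpha_m
#'   level (nnode x dim).
#' @param p nodal pressure at the alpha_f level.
#' @param sfield nodal interface scaling field.
#' @param props,stab fluid properties and stabilization parameters.
#' @param dt time-step size entering tau_m.
#' @param chain list \code{(cv, ca, cp)}: derivatives of the alpha-level
#'   velocity, rate and pressure with respect to the step-(n+1) rate unknowns.
#' @param fnod optional nodal body-force matrix (overrides
#'   \code{props$body_force}).
#' @param jacobian assemble the Jacobian blocks too?
#' @return list with \code{Rm} (dim*nnode), \code{Rc} (nnode) and, when
#'   requested, a \code{dgCMatrix} \code{J} of size (dim+1)*nnode with
#'   pressure dofs trailing.
#' @export
assemble_fluid <- function(mesh, v, vdot, p, sfield, props, stab, dt,
                           chain = list(cv = 1, ca = 1, cp = 1),
                           fnod = NULL, jacobian = TRUE, t = 0) {
  n <- nrow(mesh$nodes); d <- mesh$dim
  if (is.null(fnod)) fnod <- .nodal_body_force(props, mesh, t)
  out <- cpp_assemble_fluid(mesh$nodes, mesh$elem - 1L, mesh$elem_type,
                            v, vdot, p, sfield, fnod,
                            props$rho, props$mu, dt, stab$CI, stab$CT,
                            chain$cv, chain$ca, chain$cp, jacobian)
  res <- list(Rm = as.vector(out$Rm), Rc = as.vector(out$Rc))
  if (jacobian)
    res$J <- cpp_coo_to_csc(out$i, out$j, out$x, (d + 1L) * n)
  res
}

## ---- inflow profiles -------------------------------------------------------

#' Ramped inlet pressure for the closed-valve benchmark
#'
#' Linear ramp to \code{p_max} over \code{t_ramp}, then constant (continuous
#' at the junction). Units follow the case (CGS: dyne/cm^2).
#' @export
ramp_pressure <- function(t, p_max = 3e5, t_ramp = 0.1) {
  stopifnot(all(t >= 0))
  ifelse(t < t_ramp, p_max * t / t_ramp, p_max)
}

#' Pulsatile parabolic inlet profile for the open-valve benchmark
#'
#' \eqn{v_x = V_0 \, 4y(H-y)/H^2 \cdot (1 - \cos(2\pi t/T))/2}. The amplitude
#' and period are configurable; the default \code{V0} realizes a peak-velocity
#' Reynolds number of 110 with the benchmark's fluid (rho = 100, mu = 10, H =
#' 1.61 in CGS).
#' @export
parabolic_pulsatile <- function(t, y, V0 = 110 * 10 / (100 * 1.61), H = 1.61,
                                period = 1) {
  V0 * 4 * y * (H - y) / H^2 * 0.5 * (1 - cos(2 * pi * t / period))
}

#' Inlet profile for the oscillating-leaflet benchmark
#'
#' \eqn{v^f = 15.0\, y (2 - y) \sin(2\pi t)\, \hat e_x} (SI units of the
#' case; y in meters, t in seconds).
#' @export
leaflet_profile <- function(t, y) 15.0 * y * (2 - y) * sin(2 * pi * t)

#' Plug-flow inlet speed from a flow-rate waveform
#'
#' Returns the inward normal speed \code{Q(t)/A} for a prescribed flow rate.
#' @export
plug_flow <- function(t, Q, A) {
  qv <- if (is.function(Q)) Q(t) else Q
  qv / A
}
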