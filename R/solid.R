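## Hyperelastic constitutive models and the immersed-solid residual with the
## artificial-fluid correction. The solid weak form lives on the current
## configuration; integrals are evaluated by pulling back to the reference
## element with the same quadrature (identical values), so the reference
## coordinates never change while displacements carry the motion.

#' Compressible Neo-Hookean material
#'
#' Strain energy \eqn{\psi = \mu/2 (I_1 - 3) - \mu \ln J + \lambda/2 (\ln J)^2}
#' with Lame constants from Young's modulus and Poisson ratio.
#' @param E Young's modulus (pressure units); \code{nu} Poisson ratio.
#' @export
material_neo_hookean <- function(E, nu) {
  stopifnot(E > 0, nu > -1, nu < 0.5)
  mu <- E / (2 * (1 + nu)); lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  structure(list(type = 1L, params = c(mu, lambda), E = E, nu = nu,
                 label = "compressible neo-Hookean"), class = "ifsi_material")
}

#' Uncoupled (nearly-incompressible) Neo-Hookean material
#'
#' \eqn{\psi = C_0/2 (\bar I_1 - 3) + \kappa_s/2 (\tfrac12 (J^2-1) - \ln J)}
#' with \eqn{\bar I_1 = J^{-2/3} I_1}; Cauchy stress
#' \eqn{\sigma = (C_0/J)\,\mathrm{dev}\bar B + (\kappa_s/2)(J - 1/J) I}.
#' @param C0 shear-like modulus; \code{kappa_s} bulk-like modulus (pressure).
#' @export
material_uncoupled_neo_hookean <- function(C0, kappa_s) {
  stopifnot(C0 > 0, kappa_s > 0)
  structure(list(type = 2L, params = c(C0, kappa_s), C0 = C0, kappa_s = kappa_s,
                 label = "uncoupled neo-Hookean"), class = "ifsi_material")
}

#' Circumferential-fiber material
#'
#' Second Piola-Kirchhoff stress \eqn{S = \mu_s \hat e_\Theta \otimes
#' \hat e_\Theta}: a continuous distribution of concentric fibers stiff in the
#' reference circumferential direction. Note \eqn{\sigma \ne 0} at \eqn{F = I}
#' (a prestress); it is this internal stress that generates the non-trivial
#' equilibrium pressure of the immersed-annulus benchmark.
#' @param mu_s fiber modulus (pressure units).
#' @export
material_fiber <- function(mu_s) {
  stopifnot(mu_s > 0)
  structure(list(type = 3L, params = c(mu_s), mu_s = mu_s,
                 label = "circumferential fiber"), class = "ifsi_material")
}

#' @export
print.ifsi_material <- function(x, ...) {
  cat(sprintf("ifsi material: %s (%s)\n", x$label,
              paste(signif(x$params, 6), collapse = ", ")))
  invisible(x)
}

.embed_F <- function(F) {
  # plane strain embedding for 2D deformation gradients
  d <- nrow(F)
  if (d == 3) return(F)
  F3 <- diag(3); F3[1:2, 1:2] <- F
  F3
}

#' Cauchy stress of a hyperelastic material
#'
#' \eqn{\sigma = (2/J) F (\partial\psi/\partial C) F^T}, evaluated in closed
#' form per model (2D arguments are treated as plane strain).
#'
#' @param material from one of the material constructors.
#' @param F deformation gradient (2x2 or 3x3), det F > 0.
#' @param e_ref reference fiber direction (fiber material only; unit vector).
#' @export
cauchy_stress <- function(material, F, e_ref = NULL) {
  d <- nrow(F)
  J <- det(F)
  if (J <= 0) stop("element inversion: det F <= 0")
  if (material$type == 1L) {
    mu <- material$params[1]; lambda <- material$params[2]
    F3 <- .embed_F(F); B <- F3 %*% t(F3)
    sig <- (mu / J) * (B - diag(3)) + (lambda * log(J) / J) * diag(3)
    sig[seq_len(d), seq_len(d), drop = FALSE]
  } else if (material$type == 2L) {
    C0 <- material$params[1]; kap <- material$params[2]
    F3 <- .embed_F(F); Bbar <- J^(-2 / 3) * (F3 %*% t(F3))
    dev <- Bbar - (sum(diag(Bbar)) / 3) * diag(3)
    sig <- (C0 / J) * dev + (kap / 2) * (J - 1 / J) * diag(3)
    sig[seq_len(d), seq_len(d), drop = FALSE]
  } else {
    if (is.null(e_ref)) stop("fiber material requires a reference direction")
    fe <- as.vector(F %*% e_ref)
    (material$mu_s / J) * tcrossprod(fe)
  }
}

#' Strain-energy density of a hyperelastic material
#' @export
strain_energy_density <- function(material, F, e_ref = NULL) {
  J <- det(F)
  if (J <= 0) stop("element inversion: det F <= 0")
  F3 <- .embed_F(F)
  I1 <- sum(F3^2)
  if (material$type == 1L) {
    mu <- material$params[1]; lambda <- material$params[2]
    mu / 2 * (I1 - 3) - mu * log(J) + lambda / 2 * log(J)^2
  } else if (material$type == 2L) {
    C0 <- material$params[1]; kap <- material$params[2]
    C0 / 2 * (J^(-2 / 3) * I1 - 3) + kap / 2 * (0.5 * (J^2 - 1) - log(J))
  } else {
    # psi = mu_s/2 (e.C e - 1): quadratic in the fiber stretch, S = mu_s e x e
    Cg <- crossprod(F)
    material$mu_s / 2 * (sum(e_ref * (Cg %*% e_ref)) - 1)
  }
}

#' Solid state constructor
#'
#' Holds the reference mesh, material, initial density and the displacement /
#' velocity / acceleration DOF vectors (nnode x dim each).
#'
#' @param mesh solid mesh (role "solid").
#' @param material hyperelastic material.
#' @param rho0 reference density.
#' @param clamped nodes held fixed (e.g. the beam base); integer vector or a
#'   boundary tag name.
#' @export
solid_state <- function(mesh, material, rho0, clamped = NULL) {
  n <- nrow(mesh$nodes); d <- mesh$dim
  if (is.character(clamped)) clamped <- boundary_nodes(mesh, clamped)
  if (material$type == 3L && is.null(mesh$e_theta))
    stop("fiber material requires a mesh with reference fiber directions")
  list(mesh = mesh, material = material, rho0 = rho0,
       clamped = as.integer(clamped),
       u = matrix(0, n, d), ud = matrix(0, n, d), udd = matrix(0, n, d))
}

#' Assemble the immersed-solid residual and tangent
#'
#' The weak form on the current solid configuration: inertia with the
#' fluid-solid density difference (current solid density \eqn{\rho_0/J}),
#' internal forces of the hyperelastic model, and subtraction of the
#' artificial-fluid viscous work \eqn{2\mu_f \epsilon(w):\epsilon(v^f)} where
#' the fluid velocity on the solid is the (constraint-interpolated) solid
#' nodal velocity differentiated with solid shape functions. The tangent is
#' the consistent derivative with respect to the step-(n+1) acceleration
#' through the generalized-alpha chain factors \code{(fu, fv, fa)}.
#'
#' @param solid from \code{\link{solid_state}}.
#' @param u,ud,udd evaluation-level displacement, velocity, acceleration.
#' @param fluid_props fluid properties (density and viscosity of the
#'   artificial fluid).
#' @param chain list \code{(fu, fv, fa)}.
#' @param body_force constant acceleration vector.
#' @param jacobian assemble the tangent?
#' @export
assemble_immersed_solid <- function(solid, u, ud, udd, fluid_props,
                                    chain = list(fu = 1, fv = 1, fa = 1),
                                    body_force = NULL, jacobian = TRUE) {
  mesh <- solid$mesh; d <- mesh$dim; n <- nrow(mesh$nodes)
  if (is.null(body_force)) body_force <- rep(0, d)
  eth <- if (solid$material$type == 3L) mesh$e_theta else matrix(0, 0, d)
  out <- cpp_assemble_solid(mesh$nodes, mesh$elem - 1L, mesh$elem_type,
                            u, ud, udd,
                            solid$material$type, solid$material$params, eth,
                            solid$rho0, fluid_props$rho, fluid_props$mu,
                            as.numeric(body_force),
                            chain$fu, chain$fv, chain$fa, jacobian)
  res <- list(Rs = as.vector(out$Rs))
  if (jacobian)
    res$K <- cpp_coo_to_csc(out$i, out$j, out$x, d * n)
  res
}

#' Total strain energy of a solid displacement state
#'
#' Element-wise quadrature of the strain-energy density over the reference
#' configuration; the internal-force part of the residual is its gradient.
#' @export
total_strain_energy <- function(solid, u, quad_order = 2L) {
  mesh <- solid$mesh
  q <- quadrature_rule(mesh$elem_type, quad_order)
  acc <- 0
  for (e in seq_len(nrow(mesh$elem))) {
    conn <- mesh$elem[e, ]
    X <- mesh$nodes[conn, , drop = FALSE]
    U <- u[conn, , drop = FALSE]
    for (iq in seq_along(q$w)) {
      d <- elem_shape(mesh$elem_type, q$points[iq, ])
      J0 <- crossprod(X, d$dN)
      dNdX <- d$dN %*% solve(J0)
      F <- diag(mesh$dim) + crossprod(U, dNdX)
      eref <- NULL
      if (solid$material$type == 3L) {
        eref <- as.vector(crossprod(mesh$e_theta[conn, , drop = FALSE], d$N))
        eref <- eref / sqrt(sum(eref^2))
      }
      acc <- acc + q$w[iq] * det(J0) *
        strain_energy_density(solid$material, F, eref)
    }
  }
  acc
}
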