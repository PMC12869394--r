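## FSI constraint matrix: fluid shape functions evaluated at the solid nodes.
## The distributed Lagrange multiplier collapses to nodal delta functions, so
## interpolation (fluid -> solid velocity) and force spreading (solid residual
## -> fluid momentum) are exact transposes of each other through one sparse
## operator of shape (fluid velocity DOFs) x (solid velocity DOFs).

#' Build the FSI constraint matrix
#'
#' For every solid node, locate it in the fluid mesh and record the fluid
#' nodal basis values of the host element; a node outside the fluid mesh is
#' assigned to the nearest element with extrapolated (possibly negative or
#' > 1) basis values, mimicking leaflets that protrude beyond the vessel, up
#' to a parametric cap beyond which the run aborts. Rebuilt whenever the
#' solid moves (each Newton iteration by default).
#'
#' @param locator fluid-mesh point locator (\code{\link{point_locator}}).
#' @param solid_positions current solid node coordinates.
#' @param max_extrap parametric extrapolation cap (reference units).
#' @return list with sparse \code{C} (nv x ns), per-node \code{elem} and
#'   \code{xi}, and \code{outside} (logical: extrapolated nodes).
#' @export
build_constraint_matrix <- function(locator, solid_positions,
                                    max_extrap = 0.5) {
  mesh <- locator$mesh
  d <- mesh$dim; nen <- ncol(mesh$elem)
  ns <- nrow(solid_positions); nnf <- nrow(mesh$nodes)
  lp <- locate_point(locator, solid_positions, extrapolate = TRUE,
                     max_extrap = max_extrap)
  Nvals <- matrix(0, ns, nen)
  outside <- logical(ns)
  for (b in seq_len(ns)) {
    sh <- elem_shape(mesh$elem_type, lp$xi[b, ])
    Nvals[b, ] <- sh$N
    outside[b] <- any(lp$xi[b, ] < -1 - 1e-9) || any(lp$xi[b, ] > 1 + 1e-9)
  }
  conn <- mesh$elem[lp$elem, , drop = FALSE]          # ns x nen
  # rows: fluid velocity dof (A,i); cols: solid velocity dof (B,i)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (i in seq_len(d)) {
    rows <- c(rows, as.vector(t(d * (conn - 1L) + i)))
    cols <- c(cols, rep(d * (seq_len(ns) - 1L) + i, each = nen))
    vals <- c(vals, as.vector(t(Nvals)))
  }
  C <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(d * nnf, d * ns))
  list(C = C, elem = lp$elem, xi = lp$xi, outside = outside, dim = d)
}

#' Interpolate fluid velocity to the solid nodes
#'
#' The nodal-interpolation projection: solid node velocities are the fluid
#' velocity field evaluated at the solid node positions.
#'
#' @param Cl from \code{\link{build_constraint_matrix}}.
#' @param V fluid velocity DOF vector (length nv, component-fastest).
#' @return solid velocity DOF vector (length ns).
#' @export
interpolate_to_solid <- function(Cl, V) {
  as.vector(Matrix::crossprod(Cl$C, V))
}

#' Spread solid residuals to the fluid DOFs
#'
#' The force-spreading transpose: with the multiplier eliminated nodally,
#' the solid momentum residual lands on the fluid momentum equations as
#' \code{C \%*\% Rs}.
#' @export
spread_to_fluid <- function(Cl, Rs) {
  as.vector(Cl$C %*% Rs)
}
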