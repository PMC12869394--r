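## Reference elements, quadrature, isoparametric mapping, point location,
## and error norms. Reference domains: [-1,1]^d for quad4/hex8, the unit
## simplex for tri3/tet4. First-order Lagrange bases only.

#' Shape functions and parametric gradients at a point
#'
#' @param type element type label (\code{quad4}, \code{hex8}, \code{tri3},
#'   \code{tet4}).
#' @param xi parametric point.
#' @return list with \code{N} (length nen) and \code{dN} (nen x dim).
#' @export
elem_shape <- function(type, xi) {
  switch(type,
    quad4 = {
      x <- xi[1]; y <- xi[2]
      list(N = 0.25 * c((1 - x) * (1 - y), (1 + x) * (1 - y),
                        (1 + x) * (1 + y), (1 - x) * (1 + y)),
           dN = 0.25 * cbind(c(-(1 - y), (1 - y), (1 + y), -(1 + y)),
                             c(-(1 - x), -(1 + x), (1 + x), (1 - x))))
    },
    hex8 = {
      sx <- c(-1, 1, 1, -1, -1, 1, 1, -1)
      sy <- c(-1, -1, 1, 1, -1, -1, 1, 1)
      sz <- c(-1, -1, -1, -1, 1, 1, 1, 1)
      a <- 1 + sx * xi[1]; b <- 1 + sy * xi[2]; cc <- 1 + sz * xi[3]
      list(N = 0.125 * a * b * cc,
           dN = 0.125 * cbind(sx * b * cc, a * sy * cc, a * b * sz))
    },
    tri3 = list(N = c(1 - xi[1] - xi[2], xi[1], xi[2]),
                dN = rbind(c(-1, -1), c(1, 0), c(0, 1))),
    tet4 = list(N = c(1 - sum(xi), xi[1], xi[2], xi[3]),
                dN = rbind(c(-1, -1, -1), diag(3))),
    stop("unsupported element type: ", type))
}

.gauss1d <- function(n) {
  # Golub-Welsch via symmetric eigen of the Jacobi matrix
  if (n == 1L) return(list(x = 0, w = 2))
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  E <- eigen(pracma_tridiag(n, b), symmetric = TRUE)
  list(x = E$values, w = 2 * E$vectors[1, ]^2)
}

pracma_tridiag <- function(n, b) {
  M <- matrix(0, n, n)
  M[cbind(seq_len(n - 1L), 2:n)] <- b
  M[cbind(2:n, seq_len(n - 1L))] <- b
  M
}

#' Quadrature rule on the reference element
#'
#' Tensor-product Gauss-Legendre for quads/hexes (\code{order} = points per
#' axis, exact for degree 2*order-1 per axis); standard symmetric rules for
#' simplices (order 1 or 2).
#' @export
quadrature_rule <- function(type, order = 2L) {
  order <- as.integer(order)
  if (type %in% c("quad4", "hex8")) {
    d <- if (type == "quad4") 2L else 3L
    g <- .gauss1d(order)
    idx <- do.call(expand.grid, rep(list(seq_len(order)), d))
    pts <- matrix(g$x[as.matrix(idx)], nrow(idx), d)
    w <- apply(matrix(g$w[as.matrix(idx)], nrow(idx), d), 1, prod)
    list(points = pts, w = w)
  } else if (type == "tri3") {
    if (order <= 1L) list(points = matrix(c(1/3, 1/3), 1), w = 0.5)
    else list(points = rbind(c(1/6, 1/6), c(2/3, 1/6), c(1/6, 2/3)),
              w = rep(1/6, 3))
  } else if (type == "tet4") {
    if (order <= 1L) list(points = matrix(rep(0.25, 3), 1), w = 1/6)
    else {
      a <- (5 - sqrt(5)) / 20; b <- (5 + 3 * sqrt(5)) / 20
      list(points = rbind(c(a, a, a), c(b, a, a), c(a, b, a), c(a, a, b)),
           w = rep(1/24, 4))
    }
  } else stop("unsupported element type: ", type)
}

#' Element metric tensor
#'
#' \eqn{G_{ij} = \sum_k (\partial \xi_k/\partial x_i)(\partial \xi_k/\partial x_j)},
#' the covariant metric of the inverse isoparametric map, used by the VMS
#' stabilization coefficients. Symmetric positive definite for a valid element.
#'
#' @param coords element node coordinates (nen x dim).
#' @param type element type label.
#' @param xi parametric evaluation point.
#' @export
metric_tensor <- function(coords, type, xi) {
  d <- elem_shape(type, xi)
  J <- crossprod(coords, d$dN)        # J_ij = dx_i/dxi_j
  if (abs(det(J)) < .Machine$double.eps * max(abs(J))^nrow(J) || det(J) <= 0)
    stop("degenerate element: singular isoparametric Jacobian")
  Jinv <- solve(J)                    # dxi/dx
  crossprod(Jinv)                     # G = Jinv^T Jinv
}

#' Map a parametric point to physical coordinates
#' @export
map_to_physical <- function(coords, type, xi) {
  as.vector(crossprod(coords, elem_shape(type, xi)$N))
}

#' Point locator for a mesh
#'
#' Builds an axis-aligned bounding-box grid over the elements; queries invert
#' the isoparametric map by Newton iteration. A point on a shared facet is
#' assigned to the lowest-numbered incident element.
#'
#' @param mesh an \code{ifsi_mesh}.
#' @return an opaque locator object for \code{\link{locate_point}}.
#' @export
point_locator <- function(mesh) {
  loc <- cpp_build_locator(mesh$nodes, mesh$elem - 1L, mesh$elem_type)
  structure(list(ptr = loc, mesh = mesh), class = "ifsi_locator")
}

#' Locate points in a mesh
#'
#' @param locator from \code{\link{point_locator}}.
#' @param x matrix of query points (npts x dim) or a single point.
#' @param tol parametric tolerance for the inside test.
#' @param extrapolate if TRUE, points outside the mesh are assigned to the
#'   nearest candidate element with extrapolated parametric coordinates
#'   (capped at \code{max_extrap} reference units beyond the element).
#' @param max_extrap abort threshold for parametric extrapolation distance.
#' @return list with integer \code{elem} (0 where outside and
#'   \code{extrapolate = FALSE}) and \code{xi} matrix.
#' @export
locate_point <- function(locator, x, tol = 1e-10, extrapolate = FALSE,
                         max_extrap = 0.5) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  res <- cpp_locate(locator$ptr, x, tol, extrapolate, max_extrap)
  if (any(res$failed))
    stop(sprintf("point location failed for point (%s)",
                 paste(signif(x[which(res$failed)[1], ], 6), collapse = ", ")))
  list(elem = res$elem, xi = res$xi)
}

#' Interpolate a nodal field at arbitrary points
#' @export
interp_field <- function(locator, field, x, extrapolate = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(field))) field <- matrix(field, ncol = 1)
  lp <- locate_point(locator, x, extrapolate = extrapolate)
  mesh <- locator$mesh
  out <- matrix(NA_real_, nrow(x), ncol(field))
  for (i in seq_len(nrow(x))) {
    if (lp$elem[i] == 0L) next
    N <- elem_shape(mesh$elem_type, lp$xi[i, ])$N
    out[i, ] <- crossprod(field[mesh$elem[lp$elem[i], ], , drop = FALSE], N)
  }
  drop(out)
}

.norm_quad <- function(field, exact, mesh, quad_order, gradient) {
  if (is.null(dim(field))) field <- matrix(field, ncol = 1)
  nc <- ncol(field)
  q <- quadrature_rule(mesh$elem_type, quad_order)
  shp <- lapply(seq_along(q$w), function(iq) elem_shape(mesh$elem_type, q$points[iq, ]))
  acc <- 0
  for (e in seq_len(nrow(mesh$elem))) {
    conn <- mesh$elem[e, ]
    X <- mesh$nodes[conn, , drop = FALSE]
    U <- field[conn, , drop = FALSE]
    for (iq in seq_along(q$w)) {
      d <- shp[[iq]]
      J <- crossprod(X, d$dN)
      detJ <- det(J)
      xq <- as.vector(crossprod(X, d$N))
      if (!gradient) {
        diffv <- as.vector(crossprod(U, d$N)) - exact(xq)
        acc <- acc + q$w[iq] * detJ * sum(diffv^2)
      } else {
        dNdx <- d$dN %*% solve(J)          # nen x dim
        gh <- crossprod(U, dNdx)           # nc x dim
        ge <- exact(xq)                    # nc x dim exact gradient
        if (is.null(dim(ge))) ge <- matrix(ge, nc, mesh$dim, byrow = (nc == 1L))
        acc <- acc + q$w[iq] * detJ * sum((gh - ge)^2)
      }
    }
  }
  sqrt(acc)
}

#' L2 norm of the error of a nodal field against an exact solution
#'
#' @param field nodal values (nnode or nnode x ncomp).
#' @param exact function of a physical point returning the exact value(s).
#' @param mesh the mesh carrying the field.
#' @param quad_order quadrature order used element-wise.
#' @export
l2_error <- function(field, exact, mesh, quad_order = 3L)
  .norm_quad(field, exact, mesh, quad_order, gradient = FALSE)

#' H1 seminorm of the error against an exact gradient
#'
#' @param exact_grad function returning the exact gradient (ncomp x dim).
#' @export
h1_seminorm_error <- function(field, exact_grad, mesh, quad_order = 3L)
  .norm_quad(field, exact_grad, mesh, quad_order, gradient = TRUE)
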