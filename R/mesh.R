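#' @useDynLib ifsi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as is new
#' @importFrom stats coef lm setNames
#' @importClassesFrom Matrix dgCMatrix
NULL

## Element node orderings follow VTK conventions:
##   quad4: counter-clockwise on [-1,1]^2
##   hex8 : bottom quad CCW then top quad CCW on [-1,1]^3
##   tri3 / tet4: unit simplex, vertices in index order
## All node/element indices exposed to users are 1-based (R convention).

.ifsi_elem_info <- list(
  quad4 = list(dim = 2L, nen = 4L, facet_type = "line2", nfn = 2L),
  hex8  = list(dim = 3L, nen = 8L, facet_type = "quad4", nfn = 4L),
  tri3  = list(dim = 2L, nen = 3L, facet_type = "line2", nfn = 2L),
  tet4  = list(dim = 3L, nen = 4L, facet_type = "tri3",  nfn = 3L)
)

new_mesh <- function(dim, nodes, elem, elem_type, boundary, role = "fluid",
                     extra = list()) {
  m <- c(list(dim = as.integer(dim),
              nodes = nodes,
              elem = elem,
              elem_type = elem_type,
              boundary = boundary,
              role = role),
         extra)
  class(m) <- "ifsi_mesh"
  m
}

#' @export
print.ifsi_mesh <- function(x, ...) {
  cat(sprintf("ifsi mesh (%s): %dD, %d nodes, %d '%s' elements, %d boundary facets\n",
              x$role, x$dim, nrow(x$nodes), nrow(x$elem), x$elem_type,
              nrow(x$boundary$facets)))
  if (length(x$boundary$tag_names))
    cat("  boundary tags:", paste(names(x$boundary$tag_names), collapse = ", "), "\n")
  invisible(x)
}

#' Structured Cartesian grid
#'
#' Builds a uniform quadrilateral (2D) or hexahedral (3D) mesh of an
#' axis-aligned box, with boundary facets tagged by face
#' (\code{left}/\code{right}/\code{bottom}/\code{top} and, in 3D,
#' \code{back}/\code{front} for the z extremes).
#'
#' @param extents list of per-axis \code{c(min, max)} (2 or 3 axes).
#' @param counts integer vector of per-axis element counts.
#' @param role \code{"fluid"} or \code{"solid"}.
#' @return an \code{ifsi_mesh}.
#' @examples
#' m <- build_cartesian_grid(list(c(0, 1), c(0, 1)), c(16, 16))
#' nrow(m$elem)   # 256
#' @export
build_cartesian_grid <- function(extents, counts, role = "fluid") {
  dim <- length(extents)
  if (!dim %in% 2:3 || length(counts) != dim)
    stop("invalid geometry: extents must list 2 or 3 axes matching counts")
  counts <- as.integer(counts)
  if (any(counts < 1L)) stop("invalid geometry: element counts must be >= 1")
  lo <- vapply(extents, `[`, 0, 1); hi <- vapply(extents, `[`, 0, 2)
  if (any(hi <= lo)) stop("invalid geometry: degenerate extents (max <= min)")

  axes <- lapply(seq_len(dim), function(k) seq(lo[k], hi[k], length.out = counts[k] + 1L))
  if (dim == 2L) {
    nx <- counts[1]; ny <- counts[2]
    nodes <- cbind(rep(axes[[1]], times = ny + 1L),
                   rep(axes[[2]], each = nx + 1L))
    nid <- function(i, j) i + (nx + 1L) * (j - 1L)   # i in 1..nx+1
    i <- rep(seq_len(nx), times = ny); j <- rep(seq_len(ny), each = nx)
    elem <- cbind(nid(i, j), nid(i + 1L, j), nid(i + 1L, j + 1L), nid(i, j + 1L))
    jj <- seq_len(ny); ii <- seq_len(nx)
    facets <- rbind(
      cbind(nid(1L, jj + 1L), nid(1L, jj)),                 # left  (outward -x)
      cbind(nid(nx + 1L, jj), nid(nx + 1L, jj + 1L)),       # right
      cbind(nid(ii, 1L), nid(ii + 1L, 1L)),                 # bottom
      cbind(nid(ii + 1L, ny + 1L), nid(ii, ny + 1L)))       # top
    tag <- rep(1:4, times = c(ny, ny, nx, nx))
    tag_names <- c(left = 1L, right = 2L, bottom = 3L, top = 4L)
    et <- "quad4"
  } else {
    nx <- counts[1]; ny <- counts[2]; nz <- counts[3]
    nodes <- cbind(rep(axes[[1]], times = (ny + 1L) * (nz + 1L)),
                   rep(rep(axes[[2]], each = nx + 1L), times = nz + 1L),
                   rep(axes[[3]], each = (nx + 1L) * (ny + 1L)))
    nid <- function(i, j, k) i + (nx + 1L) * ((j - 1L) + (ny + 1L) * (k - 1L))
    i <- rep(seq_len(nx), times = ny * nz)
    j <- rep(rep(seq_len(ny), each = nx), times = nz)
    k <- rep(seq_len(nz), each = nx * ny)
    elem <- cbind(nid(i, j, k), nid(i + 1L, j, k), nid(i + 1L, j + 1L, k), nid(i, j + 1L, k),
                  nid(i, j, k + 1L), nid(i + 1L, j, k + 1L), nid(i + 1L, j + 1L, k + 1L),
                  nid(i, j + 1L, k + 1L))
    fl <- list(); tg <- integer(0)
    grid2 <- function(nu, nv) list(u = rep(seq_len(nu), times = nv), v = rep(seq_len(nv), each = nu))
    g <- grid2(ny, nz)  # left/right faces
    fl[[1]] <- cbind(nid(1L, g$u, g$v), nid(1L, g$u, g$v + 1L), nid(1L, g$u + 1L, g$v + 1L), nid(1L, g$u + 1L, g$v))
    fl[[2]] <- cbind(nid(nx + 1L, g$u, g$v), nid(nx + 1L, g$u + 1L, g$v), nid(nx + 1L, g$u + 1L, g$v + 1L), nid(nx + 1L, g$u, g$v + 1L))
    g <- grid2(nx, nz)  # bottom/top (y extremes)
    fl[[3]] <- cbind(nid(g$u, 1L, g$v), nid(g$u + 1L, 1L, g$v), nid(g$u + 1L, 1L, g$v + 1L), nid(g$u, 1L, g$v + 1L))
    fl[[4]] <- cbind(nid(g$u, ny + 1L, g$v), nid(g$u, ny + 1L, g$v + 1L), nid(g$u + 1L, ny + 1L, g$v + 1L), nid(g$u + 1L, ny + 1L, g$v))
    g <- grid2(nx, ny)  # back/front (z extremes)
    fl[[5]] <- cbind(nid(g$u, g$v, 1L), nid(g$u, g$v + 1L, 1L), nid(g$u + 1L, g$v + 1L, 1L), nid(g$u + 1L, g$v, 1L))
    fl[[6]] <- cbind(nid(g$u, g$v, nz + 1L), nid(g$u + 1L, g$v, nz + 1L), nid(g$u + 1L, g$v + 1L, nz + 1L), nid(g$u, g$v + 1L, nz + 1L))
    facets <- do.call(rbind, fl)
    tag <- rep(1:6, times = c(ny * nz, ny * nz, nx * nz, nx * nz, nx * ny, nx * ny))
    tag_names <- c(left = 1L, right = 2L, bottom = 3L, top = 4L, back = 5L, front = 6L)
    et <- "hex8"
  }
  new_mesh(dim, nodes, elem, et,
           list(facets = facets, tag = tag, tag_names = tag_names), role)
}

#' Closed annular solid strip
#'
#' Quadrilateral mesh of a circular annulus, periodic in the circumferential
#' direction (the strip's short ends are identified). The per-node reference
#' circumferential fiber direction \code{e_theta = (-sin(theta), cos(theta))}
#' is stored analytically for the circumferential-fiber material.
#'
#' @param R inner radius, \code{w} thickness, both > 0.
#' @param n_circ,n_thick circumferential / through-thickness element counts.
#' @param center annulus center (length-2).
#' @export
build_annulus_solid <- function(R, w, n_circ, n_thick, center = c(0, 0)) {
  if (R <= 0 || w <= 0) stop("invalid geometry: R and w must be positive")
  n_circ <- as.integer(n_circ); n_thick <- as.integer(n_thick)
  if (n_circ < 3L) stop("invalid geometry: n_circ must be >= 3")
  if (n_thick < 1L) stop("invalid geometry: n_thick must be >= 1")
  theta <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  radii <- R + w * (0:n_thick) / n_thick
  nodes <- cbind(center[1] + rep(radii, each = n_circ) * cos(theta),
                 center[2] + rep(radii, each = n_circ) * sin(theta))
  e_theta <- cbind(rep(-sin(theta), times = n_thick + 1L),
                   rep(cos(theta), times = n_thick + 1L))
  nid <- function(i, j) ((i - 1L) %% n_circ) + 1L + n_circ * (j - 1L)
  i <- rep(seq_len(n_circ), times = n_thick); j <- rep(seq_len(n_thick), each = n_circ)
  elem <- cbind(nid(i, j), nid(i, j + 1L), nid(i + 1L, j + 1L), nid(i + 1L, j))
  ii <- seq_len(n_circ)
  facets <- rbind(cbind(nid(ii + 1L, 1L), nid(ii, 1L)),                    # inner
                  cbind(nid(ii, n_thick + 1L), nid(ii + 1L, n_thick + 1L))) # outer
  new_mesh(2L, nodes, elem, "quad4",
           list(facets = facets, tag = rep(1:2, each = n_circ),
                tag_names = c(inner = 1L, outer = 2L)),
           role = "solid", extra = list(e_theta = e_theta))
}

#' Rectangular beam/leaflet strip
#'
#' Cantilever strip mesh; the base facet (y = origin y) is tagged
#' \code{clamped}.
#' @param origin lower-left corner, \code{width} x extent, \code{height} y extent.
#' @param nx,ny element counts across width / along height.
#' @export
build_beam_solid <- function(origin, width, height, nx, ny) {
  if (width <= 0 || height <= 0) stop("invalid geometry: degenerate extents")
  m <- build_cartesian_grid(list(c(origin[1], origin[1] + width),
                                 c(origin[2], origin[2] + height)),
                            c(nx, ny), role = "solid")
  names(m$boundary$tag_names)[m$boundary$tag_names == 3L] <- "clamped"
  m
}

#' Nodes on a tagged boundary
#' @export
boundary_nodes <- function(mesh, tags) {
  if (is.character(tags)) tags <- mesh$boundary$tag_names[tags]
  sort(unique(as.vector(mesh$boundary$facets[mesh$boundary$tag %in% tags, , drop = FALSE])))
}

#' Total mesh volume (area in 2D) by quadrature
#' @export
mesh_volume <- function(mesh, quad_order = 2L) {
  q <- quadrature_rule(mesh$elem_type, quad_order)
  vol <- 0
  for (iq in seq_along(q$w)) {
    d <- elem_shape(mesh$elem_type, q$points[iq, ])
    for (e in seq_len(nrow(mesh$elem))) {
      X <- mesh$nodes[mesh$elem[e, ], , drop = FALSE]
      vol <- vol + q$w[iq] * det(crossprod(X, d$dN))
    }
  }
  vol
}

#' Summed facet length/area of tagged boundary facets
#' @export
boundary_measure <- function(mesh, tags = NULL) {
  fac <- mesh$boundary$facets
  if (!is.null(tags)) {
    if (is.character(tags)) tags <- mesh$boundary$tag_names[tags]
    fac <- fac[mesh$boundary$tag %in% tags, , drop = FALSE]
  }
  tot <- 0
  for (f in seq_len(nrow(fac))) {
    X <- mesh$nodes[fac[f, ], , drop = FALSE]
    if (nrow(X) == 2L) tot <- tot + sqrt(sum((X[2, ] - X[1, ])^2))
    else if (nrow(X) == 3L) {
      v1 <- X[2, ] - X[1, ]; v2 <- X[3, ] - X[1, ]
      cr <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
              v1[1] * v2[2] - v1[2] * v2[1])
      tot <- tot + 0.5 * sqrt(sum(cr^2))
    } else { # bilinear quad facet: 2x2 quadrature on the surface patch
      q <- quadrature_rule("quad4", 2L)
      for (iq in seq_along(q$w)) {
        d <- elem_shape("quad4", q$points[iq, ])
        Jt <- crossprod(X, d$dN)  # 3x2 tangent map
        E <- crossprod(Jt)
        tot <- tot + q$w[iq] * sqrt(det(E))
      }
    }
  }
  tot
}

#' Validate a mesh
#'
#' Checks strictly positive element Jacobians at quadrature points, dense
#' 1-based node indexing (no orphan nodes), and facet connectivity bounds.
#' @return invisibly \code{TRUE}; errors otherwise.
#' @export
mesh_check <- function(mesh, quad_order = 2L) {
  q <- quadrature_rule(mesh$elem_type, quad_order)
  for (e in seq_len(nrow(mesh$elem))) {
    X <- mesh$nodes[mesh$elem[e, ], , drop = FALSE]
    for (iq in seq_along(q$w)) {
      d <- elem_shape(mesh$elem_type, q$points[iq, ])
      if (det(crossprod(X, d$dN)) <= 0)
        stop(sprintf("invalid mesh: non-positive Jacobian in element %d", e))
    }
  }
  used <- sort(unique(as.vector(mesh$elem)))
  if (used[1] != 1L || used[length(used)] != nrow(mesh$nodes) ||
      length(used) != nrow(mesh$nodes))
    stop("invalid mesh: node indices are not dense (orphan nodes present)")
  if (nrow(mesh$boundary$facets) &&
      max(mesh$boundary$facets) > nrow(mesh$nodes))
    stop("invalid mesh: boundary facet references unknown node")
  invisible(TRUE)
}
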