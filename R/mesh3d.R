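## 3D structured meshes for the falling-sphere benchmark: a tetrahedral
## cylinder (square-to-disk mapped quad disk, extruded to hexahedra, each
## split into six tetrahedra) and a hexahedral ball (cube-to-sphere map).

# smooth bijective square-to-disk map; the unit square boundary lands on the
# unit circle and interior Jacobians stay positive
.square_to_disk <- function(x, y) {
  cbind(x * sqrt(pmax(0, 1 - y^2 / 2)), y * sqrt(pmax(0, 1 - x^2 / 2)))
}

.hex_to_tets <- function(hex) {
  # six tetrahedra sharing the 1-7 diagonal (VTK hex ordering, 1-based)
  idx <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
               c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  out <- matrix(0L, nrow(hex) * 6L, 4L)
  for (k in 1:6) out[seq(k, by = 6L, length.out = nrow(hex)), ] <- hex[, idx[k, ]]
  out
}

.tet_boundary <- function(elem) {
  # faces of each tet, outward-consistent ordering
  fidx <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  faces <- matrix(0L, nrow(elem) * 4L, 3L)
  for (k in 1:4) faces[seq(k, by = 4L, length.out = nrow(elem)), ] <- elem[, fidx[k, ]]
  key <- apply(faces, 1L, function(f) paste(sort(f), collapse = "-"))
  tab <- table(key)
  faces[key %in% names(tab)[tab == 1L], , drop = FALSE]
}

#' Tetrahedral mesh of a cylinder
#'
#' Builds a structured quadrilateral disk (square-to-disk mapping), extrudes
#' it along z into hexahedra and splits each into six tetrahedra. Boundary
#' triangles are tagged \code{side}, \code{bottom} (z = 0) and \code{top}.
#'
#' @param radius,height cylinder dimensions.
#' @param n half the number of elements across the disk diameter.
#' @param nz axial element count.
#' @export
build_cylinder_tets <- function(radius, height, n = 8L, nz = 20L) {
  if (radius <= 0 || height <= 0) stop("invalid geometry: degenerate extents")
  n <- as.integer(n); nz <- as.integer(nz)
  s <- seq(-1, 1, length.out = 2L * n + 1L)
  gx <- rep(s, times = 2L * n + 1L); gy <- rep(s, each = 2L * n + 1L)
  disk <- radius * .square_to_disk(gx, gy)
  ng <- 2L * n + 1L
  nid2 <- function(i, j) i + ng * (j - 1L)
  i <- rep(seq_len(2L * n), times = 2L * n); j <- rep(seq_len(2L * n), each = 2L * n)
  quads <- cbind(nid2(i, j), nid2(i + 1L, j), nid2(i + 1L, j + 1L), nid2(i, j + 1L))
  nd <- ng * ng
  z <- seq(0, height, length.out = nz + 1L)
  nodes <- cbind(disk[rep(seq_len(nd), nz + 1L), , drop = FALSE],
                 rep(z, each = nd))
  hexes <- matrix(0L, nrow(quads) * nz, 8L)
  for (k in seq_len(nz)) {
    off <- (k - 1L) * nd
    hexes[seq_len(nrow(quads)) + (k - 1L) * nrow(quads), ] <-
      cbind(quads + off, quads + off + nd)
  }
  tets <- .hex_to_tets(hexes)
  # orientation check (all volumes positive by construction of the split)
  fac <- .tet_boundary(tets)
  r <- sqrt(nodes[, 1]^2 + nodes[, 2]^2)
  zc <- nodes[, 3]
  cls <- function(f) {
    zz <- zc[f]
    if (all(zz < 1e-9 * height)) 3L            # bottom
    else if (all(zz > height * (1 - 1e-9))) 4L # top
    else 1L                                    # side
  }
  tag <- vapply(seq_len(nrow(fac)), function(k) cls(fac[k, ]), 0L)
  new_mesh(3L, nodes, tets, "tet4",
           list(facets = fac, tag = tag,
                tag_names = c(side = 1L, bottom = 3L, top = 4L)),
           role = "fluid")
}

#' Hexahedral mesh of a ball
#'
#' Maps a structured cube grid onto the ball with the smooth cube-to-sphere
#' map; used for the (nearly rigid) falling sphere.
#'
#' @param a radius, \code{center} the ball center, \code{n} elements per
#'   cube axis.
#' @export
build_sphere_hexes <- function(a, center = c(0, 0, 0), n = 4L) {
  if (a <= 0) stop("invalid geometry: radius must be positive")
  n <- as.integer(n)
  s <- seq(-1, 1, length.out = n + 1L)
  g <- expand.grid(x = s, y = s, z = s)
  x <- g$x; y <- g$y; z <- g$z
  nodes <- cbind(
    x * sqrt(pmax(0, 1 - y^2 / 2 - z^2 / 2 + y^2 * z^2 / 3)),
    y * sqrt(pmax(0, 1 - x^2 / 2 - z^2 / 2 + x^2 * z^2 / 3)),
    z * sqrt(pmax(0, 1 - x^2 / 2 - y^2 / 2 + x^2 * y^2 / 3)))
  nodes <- a * nodes + matrix(center, nrow(nodes), 3, byrow = TRUE)
  ng <- n + 1L
  nid <- function(i, j, k) i + ng * ((j - 1L) + ng * (k - 1L))
  i <- rep(seq_len(n), times = n * n)
  j <- rep(rep(seq_len(n), each = n), times = n)
  k <- rep(seq_len(n), each = n * n)
  hexes <- cbind(nid(i, j, k), nid(i + 1L, j, k), nid(i + 1L, j + 1L, k),
                 nid(i, j + 1L, k), nid(i, j, k + 1L), nid(i + 1L, j, k + 1L),
                 nid(i + 1L, j + 1L, k + 1L), nid(i, j + 1L, k + 1L))
  # surface quads (cube faces mapped to the sphere), tagged "surface"
  fl <- list()
  grid2 <- function(nu, nv) list(u = rep(seq_len(nu), times = nv),
                                 v = rep(seq_len(nv), each = nu))
  gg <- grid2(n, n)
  fl[[1]] <- cbind(nid(1L, gg$u, gg$v), nid(1L, gg$u, gg$v + 1L),
                   nid(1L, gg$u + 1L, gg$v + 1L), nid(1L, gg$u + 1L, gg$v))
  fl[[2]] <- cbind(nid(n + 1L, gg$u, gg$v), nid(n + 1L, gg$u + 1L, gg$v),
                   nid(n + 1L, gg$u + 1L, gg$v + 1L), nid(n + 1L, gg$u, gg$v + 1L))
  fl[[3]] <- cbind(nid(gg$u, 1L, gg$v), nid(gg$u + 1L, 1L, gg$v),
                   nid(gg$u + 1L, 1L, gg$v + 1L), nid(gg$u, 1L, gg$v + 1L))
  fl[[4]] <- cbind(nid(gg$u, n + 1L, gg$v), nid(gg$u, n + 1L, gg$v + 1L),
                   nid(gg$u + 1L, n + 1L, gg$v + 1L), nid(gg$u + 1L, n + 1L, gg$v))
  fl[[5]] <- cbind(nid(gg$u, gg$v, 1L), nid(gg$u, gg$v + 1L, 1L),
                   nid(gg$u + 1L, gg$v + 1L, 1L), nid(gg$u + 1L, gg$v, 1L))
  fl[[6]] <- cbind(nid(gg$u, gg$v, n + 1L), nid(gg$u + 1L, gg$v, n + 1L),
                   nid(gg$u + 1L, gg$v + 1L, n + 1L), nid(gg$u, gg$v + 1L, n + 1L))
  fac <- do.call(rbind, fl)
  new_mesh(3L, nodes, hexes, "hex8",
           list(facets = fac, tag = rep(1L, nrow(fac)),
                tag_names = c(surface = 1L)),
           role = "solid")
}

#' Merge two meshes of the same element type into one
#'
#' Concatenates nodes, elements and boundary facets; the second mesh's tags
#' are offset and its tag names prefixed. Used to treat several disconnected
#' immersed bodies (e.g. two valve leaflets) as one solid domain.
#' @export
merge_meshes <- function(m1, m2, prefix = c("a", "b")) {
  stopifnot(m1$elem_type == m2$elem_type, m1$dim == m2$dim)
  off <- nrow(m1$nodes)
  toff <- max(m1$boundary$tag)
  tn <- c(setNames(m1$boundary$tag_names,
                   paste(prefix[1], names(m1$boundary$tag_names), sep = "_")),
          setNames(m2$boundary$tag_names + toff,
                   paste(prefix[2], names(m2$boundary$tag_names), sep = "_")))
  extra <- list()
  if (!is.null(m1$e_theta) && !is.null(m2$e_theta))
    extra$e_theta <- rbind(m1$e_theta, m2$e_theta)
  new_mesh(m1$dim, rbind(m1$nodes, m2$nodes),
           rbind(m1$elem, m2$elem + off), m1$elem_type,
           list(facets = rbind(m1$boundary$facets, m2$boundary$facets + off),
                tag = c(m1$boundary$tag, m2$boundary$tag + toff),
                tag_names = tn),
           role = m1$role, extra = extra)
}
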