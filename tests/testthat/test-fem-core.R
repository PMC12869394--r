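test_that("shape functions satisfy partition of unity and nodal delta", {
  nodes_of <- list(
    quad4 = rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1)),
    hex8 = cbind(c(-1, 1, 1, -1, -1, 1, 1, -1), c(-1, -1, 1, 1, -1, -1, 1, 1),
                 c(-1, -1, -1, -1, 1, 1, 1, 1)),
    tri3 = rbind(c(0, 0), c(1, 0), c(0, 1)),
    tet4 = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  set.seed(42)
  for (type in names(nodes_of)) {
    nd <- nodes_of[[type]]
    for (rep in 1:5) {
      xi <- if (type %in% c("quad4", "hex8")) runif(ncol(nd), -1, 1)
            else { u <- runif(ncol(nd)); u / (sum(u) + runif(1, 0.1, 1)) }
      sh <- elem_shape(type, xi)
      expect_equal(sum(sh$N), 1, tolerance = 1e-14)
      expect_equal(colSums(sh$dN), rep(0, ncol(nd)), tolerance = 1e-14,
                   ignore_attr = TRUE)
    }
    for (a in seq_len(nrow(nd))) {
      sh <- elem_shape(type, nd[a, ])
      expect_equal(sh$N, as.numeric(seq_len(nrow(nd)) == a), tolerance = 1e-14)
    }
  }
})

test_that("quadrature rules integrate polynomials to their stated order", {
  # quads: order-2 tensor Gauss is exact for degree 3 per axis
  q <- quadrature_rule("quad4", 2)
  expect_equal(sum(q$w), 4)
  for (px in 0:3) for (py in 0:3) {
    num <- sum(q$w * q$points[, 1]^px * q$points[, 2]^py)
    exact <- prod(vapply(c(px, py), function(p)
      ((1)^(p + 1) - (-1)^(p + 1)) / (p + 1), 0))
    expect_equal(num, exact, tolerance = 1e-13)
  }
  expect_equal(sum(quadrature_rule("hex8", 2)$w), 8)
  expect_equal(sum(quadrature_rule("tri3", 2)$w), 0.5)
  expect_equal(sum(quadrature_rule("tet4", 2)$w), 1 / 6, tolerance = 1e-15)
  # simplex rules: exact for degree 2 (e.g. x^2 over the unit triangle = 1/12)
  qt <- quadrature_rule("tri3", 2)
  expect_equal(sum(qt$w * qt$points[, 1]^2), 1 / 12, tolerance = 1e-14)
  # Q1 mass matrix on [-1,1]^2 against the closed form (1/9)*(4,2,1 pattern)
  M <- matrix(0, 4, 4)
  for (iq in seq_along(q$w)) {
    N <- elem_shape("quad4", q$points[iq, ])$N
    M <- M + q$w[iq] * tcrossprod(N)
  }
  Mex <- matrix(c(4, 2, 1, 2, 2, 4, 2, 1, 1, 2, 4, 2, 2, 1, 2, 4) / 9, 4, 4)
  expect_equal(M, Mex, tolerance = 1e-14)
})

test_that("metric tensor: uniform element, identity map, rotation invariance", {
  h <- 1 / 16
  m <- unit_square(16)
  G <- metric_tensor(m$nodes[m$elem[5, ], ], "quad4", c(0.3, -0.2))
  expect_equal(G, (4 / h^2) * diag(2), tolerance = 1e-9)
  expect_equal(sum(diag(G)), 8 / h^2, tolerance = 1e-9)

  ref <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))
  expect_equal(metric_tensor(ref, "quad4", c(0.1, 0.4)), diag(2),
               tolerance = 1e-14)

  th <- 0.7; Q <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  coords <- m$nodes[m$elem[3, ], ]
  G1 <- metric_tensor(coords, "quad4", c(0, 0))
  G2 <- metric_tensor(coords %*% t(Q), "quad4", c(0, 0))
  expect_equal(sort(eigen(G1)$values), sort(eigen(G2)$values),
               tolerance = 1e-10)

  degenerate <- rbind(c(0, 0), c(1, 0), c(1, 0), c(0, 0))
  expect_error(metric_tensor(degenerate, "quad4", c(0, 0)), "degenerate")
})

test_that("point location: vertices, centroids, outside, deterministic ties", {
  m <- unit_square(8)
  loc <- point_locator(m)
  # centroid of element 10
  ce <- colMeans(m$nodes[m$elem[10, ], ])
  lp <- locate_point(loc, ce)
  expect_equal(lp$elem, 10)
  expect_equal(as.vector(lp$xi), c(0, 0), tolerance = 1e-10)
  # mesh vertex: an incident element with matching corner, lowest-numbered
  v <- m$nodes[m$elem[10, 3], ]  # interior vertex shared by 4 elements
  lp <- locate_point(loc, v)
  inc <- which(apply(m$elem, 1, function(cn) any(abs(m$nodes[cn, 1] - v[1]) +
                                                 abs(m$nodes[cn, 2] - v[2]) < 1e-14)))
  expect_equal(lp$elem, min(inc))
  xb <- map_to_physical(m$nodes[m$elem[lp$elem, ], ], "quad4", lp$xi[1, ])
  expect_equal(xb, v, tolerance = 1e-10, ignore_attr = TRUE)
  # outside the bounding box
  expect_equal(locate_point(loc, c(3, -2))$elem, 0)
  # dense sweep: every interior point found and maps back
  set.seed(7)
  X <- matrix(runif(500), ncol = 2)
  lp <- locate_point(loc, X)
  expect_true(all(lp$elem > 0))
  for (i in sample(nrow(X), 20)) {
    xb <- map_to_physical(m$nodes[m$elem[lp$elem[i], ], ], "quad4", lp$xi[i, ])
    expect_equal(xb, X[i, ], tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("error norms: interpolated affine fields are exact (patch test)", {
  m <- unit_square(6)
  f0 <- rep(0, nrow(m$nodes))
  expect_equal(l2_error(f0, function(x) 1, m), 1, tolerance = 1e-13)
  expect_equal(l2_error(f0 + 3, function(x) 3, m), 0, tolerance = 1e-13)
  aff <- 2 + 3 * m$nodes[, 1] - m$nodes[, 2]
  expect_lt(l2_error(aff, function(x) 2 + 3 * x[1] - x[2], m), 1e-13)
  expect_lt(h1_seminorm_error(aff, function(x) c(3, -1), m), 1e-12)
  # vector field version
  V <- cbind(m$nodes[, 1], -m$nodes[, 2])
  expect_lt(l2_error(V, function(x) c(x[1], -x[2]), m), 1e-13)
  expect_lt(h1_seminorm_error(V, function(x) rbind(c(1, 0), c(0, -1)), m), 1e-12)
})
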