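test_that("constraint matrix holds the fluid basis values at the solid nodes", {
  m <- unit_square(8)
  loc <- point_locator(m)
  # a solid node coincident with fluid node 30: single entry 1.0
  Cl <- build_constraint_matrix(loc, m$nodes[30, , drop = FALSE])
  C <- as.matrix(Cl$C)
  expect_equal(C[2 * 29 + 1, 1], 1)
  expect_equal(sum(C[, 1] != 0), 1)
  # element centroid: four entries of 0.25
  ce <- colMeans(m$nodes[m$elem[12, ], ])
  Cl <- build_constraint_matrix(loc, matrix(ce, 1))
  expect_equal(sort(Cl$C@x), rep(0.25, 8))  # four nodes x two components
  # partition of unity: in-mesh columns sum to one
  set.seed(12)
  X <- matrix(runif(60), ncol = 2)
  Cl <- build_constraint_matrix(loc, X)
  expect_equal(unname(Matrix::colSums(Cl$C)), rep(1, 60), tolerance = 1e-12)
  expect_false(any(Cl$outside))
})

test_that("interpolation reproduces constant and affine fluid fields", {
  m <- unit_square(6)
  loc <- point_locator(m)
  set.seed(13)
  X <- matrix(runif(40), ncol = 2)
  Cl <- build_constraint_matrix(loc, X)
  # constant velocity
  Vc <- rep(c(2, -1), nrow(m$nodes))
  us <- interpolate_to_solid(Cl, Vc)
  expect_equal(matrix(us, ncol = 2, byrow = TRUE),
               matrix(rep(c(2, -1), 20), ncol = 2, byrow = TRUE),
               tolerance = 1e-12)
  # affine field is reproduced exactly by the bilinear basis
  Vaff <- as.vector(t(cbind(1 + 2 * m$nodes[, 1] - m$nodes[, 2],
                            m$nodes[, 1] + 3 * m$nodes[, 2])))
  us <- interpolate_to_solid(Cl, Vaff)
  expect_equal(matrix(us, ncol = 2, byrow = TRUE),
               cbind(1 + 2 * X[, 1] - X[, 2], X[, 1] + 3 * X[, 2]),
               tolerance = 1e-12)
})

test_that("interpolation and spreading are exact transposes; force is conserved", {
  m <- unit_square(7)
  loc <- point_locator(m)
  set.seed(14)
  X <- matrix(runif(50, 0.05, 0.95), ncol = 2)
  Cl <- build_constraint_matrix(loc, X)
  V <- rnorm(2 * nrow(m$nodes))
  lam <- rnorm(2 * nrow(X))
  expect_equal(sum(interpolate_to_solid(Cl, V) * lam),
               sum(V * spread_to_fluid(Cl, lam)), tolerance = 1e-12)
  expect_equal(spread_to_fluid(Cl, numeric(2 * nrow(X))),
               numeric(2 * nrow(m$nodes)))
  # per-component force conservation (columns sum to 1)
  Rs <- rnorm(2 * nrow(X))
  spread <- matrix(spread_to_fluid(Cl, Rs), ncol = 2, byrow = TRUE)
  Rsm <- matrix(Rs, ncol = 2, byrow = TRUE)
  expect_equal(colSums(spread), colSums(Rsm), tolerance = 1e-12)
  # unit load at a centroid spreads as 0.25 to the four corner nodes
  ce <- colMeans(m$nodes[m$elem[5, ], ])
  Cl1 <- build_constraint_matrix(loc, matrix(ce, 1))
  sp <- matrix(spread_to_fluid(Cl1, c(1, 0)), ncol = 2, byrow = TRUE)
  expect_equal(sort(sp[m$elem[5, ], 1]), rep(0.25, 4), tolerance = 1e-12)
})

test_that("rigid solid shifts move interpolated affine fields consistently", {
  m <- unit_square(9)
  loc <- point_locator(m)
  set.seed(15)
  X <- matrix(runif(30, 0.2, 0.6), ncol = 2)
  delta <- c(0.13, -0.07)
  Vaff <- as.vector(t(cbind(2 * m$nodes[, 1] + m$nodes[, 2],
                            -m$nodes[, 1] + 0.5 * m$nodes[, 2])))
  u1 <- interpolate_to_solid(build_constraint_matrix(loc, X), Vaff)
  X2 <- sweep(X, 2, delta, "+")
  u2 <- interpolate_to_solid(build_constraint_matrix(loc, X2), Vaff)
  shift <- matrix(u2 - u1, ncol = 2, byrow = TRUE)
  expect_equal(shift, matrix(rep(c(2 * delta[1] + delta[2],
                                   -delta[1] + 0.5 * delta[2]),
                                 each = 15), ncol = 2),
               tolerance = 1e-11)
})

test_that("nodes outside the fluid mesh extrapolate from the nearest element, capped", {
  m <- unit_square(4)
  loc <- point_locator(m)
  # slightly protruding node: extrapolated basis values still sum to 1
  Cl <- build_constraint_matrix(loc, matrix(c(1.05, 0.5), 1))
  expect_true(Cl$outside[1])
  expect_equal(unname(Matrix::colSums(Cl$C)), c(1, 1), tolerance = 1e-10)
  expect_true(any(Cl$C@x < 0) || any(Cl$C@x > 1))
  # far outside the cap: coupling error naming the point
  expect_error(build_constraint_matrix(loc, matrix(c(2.5, 0.5), 1)),
               "point location failed")
})
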