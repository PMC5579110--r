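test_that("interpolation operators reproduce polynomials up to their degree", {
  band <- sphere_band(17)
  ops <- sphere_ops(17)
  # partition of unity: constants map to themselves
  ones <- rep(1, band$n)
  expect_lt(max(abs(as.numeric(ops$E1 %*% ones) - 1)), 1e-13)
  expect_lt(max(abs(as.numeric(ops$E3 %*% ones) - 1)), 1e-13)
  # linear polynomial, degree 1: exact at closest points
  f1 <- band$x[, 1] + 2 * band$x[, 2] - band$x[, 3]
  want1 <- band$cp[, 1] + 2 * band$cp[, 2] - band$cp[, 3]
  expect_lt(max(abs(as.numeric(ops$E1 %*% f1) - want1)), 1e-12)
  # cubic monomial x^2 y, degree 3: matches direct per-node evaluation
  f3 <- band$x[, 1]^2 * band$x[, 2]
  want3 <- band$cp[, 1]^2 * band$cp[, 2]
  expect_lt(max(abs(as.numeric(ops$E3 %*% f3) - want3)), 1e-12)
  # degree-1 rows are convex (nonnegative weights)
  expect_gte(min(ops$E1@x), -1e-14)
})

test_that("Cartesian Laplacian is exact on quadratics and matches a stencil oracle", {
  band <- sphere_band(17)
  ops <- sphere_ops(17)
  int <- band$interior
  lap_x2 <- as.numeric(ops$L %*% band$x[, 1]^2)
  expect_lt(max(abs(lap_x2[int] - 2)), 1e-9)
  expect_lt(max(abs(as.numeric(ops$L %*% rep(3.7, band$n))[int])), 1e-9)
  # random field against direct stencil application
  set.seed(4)
  u <- rnorm(band$n)
  h2 <- band$grid$h^2
  want <- numeric(band$n)
  ii <- which(int)
  want[ii] <- (u[band$neigh[ii, 1]] + u[band$neigh[ii, 2]] +
               u[band$neigh[ii, 3]] + u[band$neigh[ii, 4]] +
               u[band$neigh[ii, 5]] + u[band$neigh[ii, 6]] - 6 * u[ii]) / h2
  expect_lt(max(abs(as.numeric(ops$L %*% u) - want)), 1e-12 / h2)
})

test_that("variable-coefficient Laplacian reduces, vanishes and is self-adjoint", {
  band <- sphere_band(17)
  ops <- sphere_ops(17)
  Lv1 <- variable_laplacian(band, rep(1, band$n))
  expect_lt(max(abs(Lv1 - ops$L)), 1e-13 / band$grid$h^2)
  Lv0 <- variable_laplacian(band, rep(0, band$n))
  expect_equal(max(abs(Lv0)), 0)
  expect_error(variable_laplacian(band, rep(-0.1, band$n)), "non-negative")
  # divergence form is self-adjoint on interior-supported vectors
  set.seed(5)
  nu <- runif(band$n, 0.2, 1)
  Lv <- variable_laplacian(band, nu)
  deep <- band$interior & rowSums(band$neigh > 0) == 6 &
    apply(band$neigh, 1, function(r) all(r == 0 | band$interior[pmax(r, 1)]))
  u <- v <- numeric(band$n)
  u[deep] <- rnorm(sum(deep))
  v[deep] <- rnorm(sum(deep))
  expect_equal(sum(u * as.numeric(Lv %*% v)), sum(v * as.numeric(Lv %*% u)),
               tolerance = 1e-12)
})

test_that("surface Laplacian annihilates constants and has the right sphere eigenvalues", {
  ops <- sphere_ops(17)
  band <- sphere_band(17)
  expect_lt(max(abs(as.numeric(ops$M %*% rep(0.3, band$n)))), 1e-10)
  errs <- sapply(c(17, 33), function(N) {
    b <- sphere_band(N)
    o <- sphere_ops(N)
    r <- sqrt(rowSums(b$x^2))
    u1 <- b$x[, 3] / r                      # Y_1 extension, eigenvalue -2
    u2 <- (3 * (b$x[, 3] / r)^2 - 1) / 2    # Y_2 extension, eigenvalue -6
    c(max(abs(as.numeric(o$M %*% u1) + 2 * u1)),
      max(abs(as.numeric(o$M %*% u2) + 6 * u2)))
  })
  # second-order convergence: halving h divides the error by ~4
  ratio <- errs[, 1] / errs[, 2]
  expect_gt(min(ratio), 3.0)
  expect_lt(max(ratio), 5.5)
  expect_lt(errs[2, 2], 0.1)  # small absolute error on the finer grid
})

test_that("incomplete stencils are hard errors", {
  g <- grid_spec(17)
  geom <- sphere_geometry()
  thin <- build_band(geom, g, half_width = 1.5 * g$h)
  expect_error(interpolation_operator(thin, 3L), "incomplete")
  # a thin band has E1 sources whose Laplacian rows are missing
  b2 <- build_band(geom, g, half_width = 2.2 * g$h)
  E1 <- interpolation_operator(b2, 1L)
  L <- cartesian_laplacian(b2)
  E3 <- tryCatch(interpolation_operator(b2, 3L), error = function(e) NULL)
  if (!is.null(E3)) {
    expect_error(surface_laplacian_operator(E1, E3, L, b2), "incomplete")
  } else {
    succeed()
  }
})

test_that("field extension makes values constant along normals", {
  band <- sphere_band(17)
  ops <- sphere_ops(17)
  r <- sqrt(rowSums(band$x^2))
  f <- band$x[, 3] / r + 0.05 * (r - 1)  # not normal-constant
  fe <- extend_field(f, ops)
  expect_true(is_extended(fe))
  # after extension, the value equals the cubic interpolant at cp
  expect_lt(max(abs(as.numeric(ops$E3 %*% fe) - fe)), 5e-3)
  expect_lt(max(abs(fe - band$cp[, 3])), 5e-3)
})
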