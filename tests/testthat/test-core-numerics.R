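test_that("grid construction enforces uniform spacing and freezes the wall mask", {
  g <- grid_create(c(32, 16), c(2, 1))
  expect_equal(g$dx, 1 / 16)
  expect_error(grid_create(c(32, 16), c(2, 1.5)), "uniform")
  w <- array(FALSE, dim = c(8, 8, 8))
  w[1, , ] <- TRUE
  g3 <- grid_create(c(8, 8, 8), c(1, 1, 1), wall_mask = w)
  expect_equal(sum(g3$wall), 64)
})

test_that("boundary specs validate patches and pair periodic sides", {
  expect_error(boundary_spec(foo = list(kind = "fixed", value = 1)), "unknown patch")
  expect_error(boundary_spec(xlo = list(kind = "fixed")), "needs a value")
  expect_error(boundary_spec(xlo = list(kind = "periodic"),
                             xhi = list(kind = "zerograd")), "pair")
})

test_that("apply_bc fills ghosts per kind and imposes wall values", {
  g <- grid_create(c(4, 4), c(1, 1), periodic = c(TRUE, FALSE))
  f <- matrix(seq_len(16), 4)
  bc <- boundary_spec(xlo = list(kind = "periodic"), xhi = list(kind = "periodic"),
                      ylo = list(kind = "fixed", value = 5.5),
                      yhi = list(kind = "zerograd"))
  p <- apply_bc(f, bc, g)
  expect_equal(p[1, 2:5], f[4, ])          # periodic: ghost = opposite plane
  expect_equal(p[2:5, 1], 2 * 5.5 - f[, 1]) # fixed: face value 5.5
  expect_equal(p[2:5, 6], f[, 4])           # zero-gradient
  gm <- grid_create(c(4, 4), c(1, 1),
                    wall_mask = matrix(c(TRUE, rep(FALSE, 15)), 4))
  pm <- apply_bc(f, default_bc(gm), gm, wall_value = 0)
  expect_equal(pm[2, 2], 0)
})

test_that("gradient is exact on linear fields and zero on constants", {
  g <- grid_create(c(16, 16), c(1, 1))
  x <- grid_centers(g, 1)
  f <- outer(x, rep(1, 16))
  gr <- gradient(f, g)
  # interior faces: exact derivative (1, 0)
  expect_equal(max(abs(gr$x[2:16, ] - 1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(gr$y)), 0)
  gc <- gradient(matrix(3.5, 16, 16), g)
  expect_equal(max(abs(gc$x[2:16, ])), 0)
})

test_that("gradient and divergence converge at second order on periodic fields", {
  err_g <- err_d <- c()
  for (n in c(32, 64, 128)) {
    g <- grid_create(c(n, n), c(1, 1), periodic = c(TRUE, TRUE))
    x <- grid_centers(g, 1)
    f <- outer(sin(2 * pi * x), rep(1, n))
    gr <- gradient(f, g)
    xf <- grid_faces(g, 1)[1:n]
    err_g <- c(err_g, max(abs(gr$x[1:n, ] - 2 * pi * cos(2 * pi * xf))))
    u <- vector_field(g)
    u$x <- outer(sin(2 * pi * grid_faces(g, 1)), rep(1, n))
    dv <- divergence(u, g)
    err_d <- c(err_d, max(abs(dv - outer(2 * pi * cos(2 * pi * x), rep(1, n)))))
  }
  slope_g <- -coef(lm(log(err_g) ~ log(c(32, 64, 128))))[[2]]
  slope_d <- -coef(lm(log(err_d) ~ log(c(32, 64, 128))))[[2]]
  expect_gt(slope_g, 1.8); expect_lt(slope_g, 2.2)
  expect_gt(slope_d, 1.8); expect_lt(slope_d, 2.2)
})

test_that("divergence vanishes for uniform and analytically solenoidal fields", {
  g <- grid_create(c(16, 16), c(1, 1))
  u <- vector_field(g, 0)
  u$x[] <- 1
  expect_equal(max(abs(divergence(u, g))), 0)
  # u = (x, -y) sampled on faces
  u$x <- outer(grid_faces(g, 1), rep(1, 16))
  u$y <- -outer(rep(1, 16), grid_faces(g, 2))
  expect_lt(max(abs(divergence(u, g))), 1e-12)
})

test_that("strain rate and deviatoric satisfy their closed forms", {
  g <- grid_create(c(16, 16), c(1, 1), periodic = c(TRUE, FALSE))
  D <- strain_rate(shear_velocity(g, 1), g)
  inner <- 3:14
  expect_equal(max(abs(D$xy[inner, inner] - 0.5)), 0, tolerance = 1e-12)
  expect_equal(max(abs(D$xx)), 0)
  expect_equal(max(abs(D$zz)), 0)
  Dp <- deviatoric(D)
  expect_lt(max(abs(Dp$xx + Dp$yy + Dp$zz)), 1e-14)
  # deviatoric of the identity vanishes (full 3-component trace, also in 2D)
  I2 <- sym_tensor_field(g, diag_value = 1)
  Ip <- deviatoric(I2)
  expect_equal(max(abs(Ip$xx)), 0)
  expect_equal(max(abs(Ip$zz)), 0)
})

test_that("Q-criterion separates shear, rotation and uniform flow", {
  g <- grid_create(c(16, 16), c(1, 1), periodic = c(FALSE, FALSE))
  inner <- 3:14
  Q <- q_criterion(shear_velocity(g, 2), g)
  expect_lt(max(abs(Q[inner, inner])), 1e-12)
  ur <- vector_field(g)
  ur$x <- -outer(rep(1, 17), grid_centers(g, 2) - 0.5)
  ur$y <- outer(grid_centers(g, 1) - 0.5, rep(1, 17))
  Qr <- q_criterion(ur, g)
  expect_equal(max(abs(Qr[inner, inner] - 1)), 0, tolerance = 1e-10)
  uu <- vector_field(g); uu$x[] <- 2; uu$y[] <- -1
  expect_lt(max(abs(q_criterion(uu, g))), 1e-12)
})
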