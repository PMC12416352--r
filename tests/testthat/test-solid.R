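test_that("solid properties enforce the incompressibility exponent and bounds", {
  p <- solid_props(G = 10, mu_s = 0.01)
  expect_equal(p$beta, 0.5)
  expect_error(solid_props(G = 10, beta = 1), "1/2")
  expect_error(solid_props(G = -1), "non-negative")
  expect_error(solid_props(G = 1, alpha_min = 0.6), "alpha_min")
})

test_that("uniform translation leaves a uniform tensor unchanged", {
  g <- grid_create(c(16, 16), c(1, 1), periodic = c(TRUE, TRUE))
  u <- vector_field(g); u$x[] <- 1; u$y[] <- 0.5
  b <- sym_tensor_field(g, diag_value = 1)
  b$xy[] <- 0.3
  b2 <- evolve_btilde(b, u, g, 0.01)
  expect_lt(max(abs(b2$xx - 1)), 1e-13)
  expect_lt(max(abs(b2$xy - 0.3)), 1e-13)
})

test_that("full-solid simple shear reproduces the closed-form deformation", {
  # B(t) for u = (gamma y, 0), B(0) = I: Bxx = 1 + (gamma t)^2, Bxy = gamma t
  g <- grid_create(c(16, 16), c(1, 1), periodic = c(TRUE, FALSE))
  gam <- 1; tend <- 0.5; dt <- 0.025
  b <- sym_tensor_field(g, diag_value = 1)
  u <- shear_velocity(g, gam)
  for (s in seq_len(round(tend / dt))) b <- evolve_btilde(b, u, g, dt)
  expect_lt(max(abs(b$xx - (1 + (gam * tend)^2))), 1e-12)
  expect_lt(max(abs(b$xy - gam * tend)), 1e-12)
  expect_lt(max(abs(b$yy - 1)), 1e-12)
})

test_that("the source integrator is second order in time (extensional flow)", {
  # u = (g x, -g y): Bxx(t) = exp(2 g t), a non-polynomial solution that
  # exposes the temporal order of the trapezoidal fixed-point pass
  g <- grid_create(c(8, 8), c(1, 1), periodic = c(FALSE, FALSE))
  gam <- 1; tend <- 0.5
  u <- vector_field(g)
  u$x <- outer(gam * grid_faces(g, 1), rep(1, 8))
  u$y <- -outer(rep(1, 8), gam * grid_faces(g, 2))
  errs <- c()
  dts <- c(0.025, 0.0125, 0.00625)
  for (dt in dts) {
    b <- sym_tensor_field(g, diag_value = 1)
    for (s in seq_len(round(tend / dt))) b <- evolve_btilde(b, u, g, dt)
    errs <- c(errs, abs(b$xx[4, 4] - exp(2 * gam * tend)))
  }
  order <- coef(lm(log(errs) ~ log(dts)))[[2]]
  expect_gt(order, 1.8)
})

test_that("rigid rotation preserves the identity tensor (objectivity)", {
  g <- grid_create(c(16, 16), c(1, 1), periodic = c(FALSE, FALSE))
  u <- vector_field(g)
  u$x <- -outer(rep(1, 17), grid_centers(g, 2) - 0.5)
  u$y <- outer(grid_centers(g, 1) - 0.5, rep(1, 17))
  b <- sym_tensor_field(g, diag_value = 1)
  for (s in seq_len(100)) b <- evolve_btilde(b, u, g, 0.005)
  expect_lt(max(abs(b$xx - 1), abs(b$xy), abs(b$yy - 1), abs(b$zz - 1)), 1e-12)
})

test_that("clipping follows the strict-threshold rule", {
  g <- grid_create(c(4, 4), c(1, 1))
  props <- solid_props(G = 1, reset = "zero")
  a <- matrix(c(0.05, 0.5, 0.1, rep(0.8, 13)), 4)
  b <- sym_tensor_field(g, diag_value = 2)
  out <- clip_btilde(b, a, props, g)
  expect_equal(out$btilde$xx[1, 1], 0)    # below threshold: zero tensor
  expect_equal(out$alpha[1, 1], 0)
  expect_equal(out$btilde$xx[2, 1], 2)    # untouched
  expect_equal(out$btilde$xx[3, 1], 2)    # exactly alpha_min: untouched
  expect_equal(out$alpha[3, 1], 0.1)
  propu <- solid_props(G = 1, reset = "unit")
  outu <- clip_btilde(b, a, propu, g)
  expect_equal(outu$btilde$xx[1, 1], 1)
  expect_equal(outu$btilde$xy[1, 1], 0)
  # tensor-only mode leaves the transported volume fraction alone
  outk <- clip_btilde(b, a, props, g, zero_alpha = FALSE)
  expect_equal(outk$alpha[1, 1], 0.05)
})

test_that("elastic force vanishes for undeformed or absent solid", {
  g <- grid_create(c(16, 16), c(1, 1), periodic = c(TRUE, TRUE))
  props <- solid_props(G = 2)
  a <- matrix(0.7, 16, 16)
  b <- sym_tensor_field(g)
  for (cn in c("xx", "yy", "zz")) b[[cn]] <- sqrt(a)  # Btilde = sqrt(alpha) I
  f <- elastic_force(b, a, props, g)
  expect_lt(max(abs(f$x), abs(f$y)), 1e-12)
  f0 <- elastic_force(sym_tensor_field(g, diag_value = 1), scalar_field(g), props, g)
  expect_equal(max(abs(f0$x), abs(f0$y)), 0)
})

test_that("a linear shear stress field gives the hand-computed uniform force", {
  # alpha = 1, Btilde_xy = gamma x  =>  force_y = G gamma (conservative flux)
  g <- grid_create(c(16, 16), c(1, 1), periodic = c(FALSE, TRUE))
  gam <- 2; G <- 3
  props <- solid_props(G = G)
  b <- sym_tensor_field(g)
  b$xy <- outer(gam * grid_centers(g, 1), rep(1, 16))
  f <- elastic_force(b, matrix(1, 16, 16), props, g)
  inner <- 3:14
  expect_equal(max(abs(f$y[inner, inner] - G * gam)), 0, tolerance = 1e-10)
})

test_that("symmetry is preserved by construction over a vortex flow", {
  g <- grid_create(c(24, 24), c(1, 1), periodic = c(TRUE, TRUE))
  u <- vortex_velocity(g)
  b <- sym_tensor_field(g, diag_value = 1)
  for (s in 1:20) b <- evolve_btilde(b, u, g, 0.002)
  # symmetric storage: only 4 independent components exist in 2D
  expect_named(b, c("xx", "xy", "yy", "zz"))
  expect_true(all(is.finite(unlist(b))))
})
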