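test_that("planar interfaces are reconstructed exactly", {
  g <- grid_create(c(16, 16, 16), c(1, 1, 1), periodic = rep(TRUE, 3))
  x <- grid_centers(g, 1)
  a <- array(rep(pmin(1, pmax(0, (0.47 - x) / g$dx + 0.5)), 16 * 16), dim = g$n)
  rec <- reconstruct_interface(a, g, rdf_iterations = 2)
  expect_gt(length(rec$cells), 0)
  expect_lt(max(abs(sweep(rec$normals, 2, c(1, 0, 0)))), 1e-6)
  expect_lt(max(abs(rec$volume_residual)), 1e-10)
  expect_lt(max(abs(sqrt(rowSums(rec$normals^2)) - 1)), 1e-12)
})

test_that("RDF refinement improves sphere normals over the Youngs estimate", {
  g <- grid_create(c(64, 64, 64), c(1, 1, 1), periodic = rep(TRUE, 3))
  a <- rasterize(particle_spec("sphere", rs = 0.25, center = c(.5, .5, .5)), g)
  angerr <- function(it) {
    r <- reconstruct_interface(a, g, rdf_iterations = it)
    cc <- arrayInd(r$cells, g$n)
    rad <- sweep((cc - 0.5) * g$dx, 2, c(.5, .5, .5))
    rad <- rad / sqrt(rowSums(rad^2))
    mean(acos(pmin(1, rowSums(rad * r$normals))) * 180 / pi)
  }
  expect_lt(angerr(2), angerr(0))
})

test_that("uniform fields have an empty interface-cell list", {
  g <- grid_create(c(8, 8), c(1, 1))
  expect_length(reconstruct_interface(scalar_field(g, 0), g)$cells, 0)
  expect_length(reconstruct_interface(scalar_field(g, 1), g)$cells, 0)
})

test_that("advection with zero velocity is the exact identity", {
  g <- grid_create(c(32, 32), c(1, 1), periodic = c(TRUE, TRUE))
  a <- rasterize(particle_spec("sphere", rs = 0.2, center = c(.5, .5, 0)), g)
  a2 <- advect_alpha(a, vector_field(g), g, dt = 0.01)
  expect_identical(as.vector(a2), as.vector(a))
})

test_that("a translated cube returns after one period with tiny shape error", {
  g <- grid_create(c(32, 32, 32), c(1, 1, 1), periodic = rep(TRUE, 3))
  a0 <- scalar_field(g)
  a0[8:15, 8:15, 8:15] <- 1
  u <- vector_field(g); u$x[] <- 1
  dt <- 0.25 * g$dx
  a <- a0
  for (s in seq_len(round(1 / dt))) a <- advect_alpha(a, u, g, dt, s %% 3)
  expect_lt(abs(sum(a) - sum(a0)) / sum(a0), 1e-10)
  expect_lt(sum(abs(a - a0)), 2)          # L1 error below two cells' volume
})

test_that("the reversed single vortex recovers the disk, improving with N", {
  l1 <- c()
  for (n in c(32, 64)) {
    g <- grid_create(c(n, n), c(1, 1), periodic = c(TRUE, TRUE))
    a0 <- rasterize(particle_spec("sphere", rs = 0.15, center = c(.5, .75, 0)), g)
    uf <- vortex_velocity(g, 1); ub <- vortex_velocity(g, -1)
    dt <- 0.1 * g$dx
    a <- a0
    nst <- round(1 / dt)
    for (s in seq_len(nst)) a <- advect_alpha(a, uf, g, dt, s %% 2)
    for (s in seq_len(nst)) a <- advect_alpha(a, ub, g, dt, s %% 2)
    l1 <- c(l1, sum(abs(a - a0)) * g$dx^2)
  }
  expect_lt(l1[2], l1[1])
})

test_that("alpha stays bounded and conserved over 1000 vortex steps", {
  g <- grid_create(c(32, 32), c(1, 1), periodic = c(TRUE, TRUE))
  a <- rasterize(particle_spec("sphere", rs = 0.15, center = c(.5, .6, 0)), g)
  v0 <- sum(a)
  u <- vortex_velocity(g)
  dt <- 0.08 * g$dx
  for (s in seq_len(1000)) {
    a <- advect_alpha(a, u, g, dt, s %% 2)
  }
  expect_true(all(a >= 0 & a <= 1))
  expect_lt(abs(sum(a) - v0) / v0, 1e-8)
})

test_that("a fully solid domain is transported as the identity", {
  g <- grid_create(c(16, 16), c(1, 1), periodic = c(TRUE, TRUE))
  a <- scalar_field(g, 1)
  u <- vortex_velocity(g)
  a2 <- advect_alpha(a, u, g, dt = 0.05 * g$dx)
  expect_lt(max(abs(a2 - 1)), 1e-12)
})

test_that("mixture viscosity blends affinely and validates inputs", {
  expect_equal(mixture_viscosity(0, 1, 10), 1)
  expect_equal(mixture_viscosity(1, 1, 10), 10)
  expect_equal(mixture_viscosity(0.5, 1, 10), 5.5)
  expect_error(mixture_viscosity(0.5, -1, 10), "non-negative")
})
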