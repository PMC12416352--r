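test_that("isosurface topology distinguishes torus and sphere", {
  g <- grid_create(c(64, 64, 64), c(1, 1, 1))
  iso_t <- isosurface(torus_field(g), g, level = 0)
  expect_equal(euler_characteristic(iso_t), 0)
  fs <- array(0, dim = g$n)
  x <- grid_centers(g, 1)
  for (k in 1:64) fs[, , k] <- sqrt(outer((x - .5)^2, (x - .5)^2, `+`) +
                                      (x[k] - .5)^2) - 0.3
  iso_s <- isosurface(fs, g, level = 0)
  expect_equal(euler_characteristic(iso_s), 2)
})

test_that("the centroid is the alpha-weighted mean, with periodic unwrap", {
  # two cells, alpha = {1, 0.5}, positions {0, 1} -> 1/3 (unit volumes)
  w <- c(1, 0.5); x <- c(0, 1)
  expect_equal(sum(w * x) / sum(w), 1 / 3)
  g <- grid_create(c(32, 32), c(1, 1), periodic = c(TRUE, FALSE))
  # grid-symmetric placement: centroid recovered to round-off
  a0 <- rasterize(particle_spec("sphere", rs = 0.15, center = c(.5, .5, 0)), g)
  expect_equal(centroid(a0, g), c(0.5, 0.5), tolerance = 1e-12)
  # off-lattice placement: limited by the rasterization, not the formula
  a <- rasterize(particle_spec("sphere", rs = 0.15, center = c(.5, .4, 0)), g)
  expect_equal(centroid(a, g), c(0.5, 0.4), tolerance = 2e-3)
  # particle straddling the periodic boundary
  a2 <- rasterize(particle_spec("sphere", rs = 0.15, center = c(0.98, .5, 0)), g)
  a2 <- a2 + rasterize(particle_spec("sphere", rs = 0.15, center = c(-0.02, .5, 0)), g)
  a2 <- pmin(a2, 1)
  xc <- centroid(array(a2, dim = g$n), g)
  expect_lt(min(abs(xc[1] - 0.98), abs(xc[1] - (0.98 - 1))), 2e-2)
})

test_that("a rigid translation has the uniform centroid velocity", {
  g <- grid_create(c(16, 16), c(1, 1))
  a <- rasterize(particle_spec("sphere", rs = 0.2, center = c(.5, .5, 0)), g)
  u <- vector_field(g); u$x[] <- 0.7; u$y[] <- -0.2
  expect_equal(centroid_velocity(a, u, g), c(0.7, -0.2))
})

test_that("orientation recovers the symmetry axis from the gyration tensor", {
  # planar ring in the yz-plane: zero variance along x -> n = x-hat, psi = 0
  th <- seq(0, 2 * pi, length.out = 201)[-1]
  ring <- list(vertices = cbind(0, 0.3 * cos(th), 0.3 * sin(th)),
               triangles = matrix(1L, 0, 3))
  o <- orientation(structure(ring, class = "isosurface"))
  expect_equal(o$psi, 0, tolerance = 1e-9)
  expect_false(o$degenerate)
  # construct-and-recover: torus cloud rotated 45 degrees about z
  cl <- torus_cloud(c(cos(pi / 4), sin(pi / 4), 0))
  o45 <- orientation(structure(list(vertices = cl), class = "isosurface"))
  expect_lt(abs(o45$psi - 45), 0.5)
  # a point set with exact octahedral symmetry has a degenerate spectrum
  set.seed(3)
  base <- matrix(rnorm(300), ncol = 3)
  perms <- do.call(rbind, lapply(list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2)),
                                 function(p) base[, p]))
  flips <- expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))
  sym <- do.call(rbind, lapply(seq_len(8), function(i)
    sweep(perms, 2, as.numeric(flips[i, ]), `*`)))
  od <- orientation(structure(list(vertices = sym), class = "isosurface"),
                    prev = c(0.6, 0.8, 0))
  expect_true(od$degenerate)
  expect_equal(od$n, c(0.6, 0.8, 0))   # previous orientation reused
})

test_that("the local frame is right-handed, orthonormal, and guards poles", {
  fr <- local_frame(c(1, 0, 0))
  expect_equal(fr$zeta, c(0, 0, 1))
  expect_equal(fr$xi, c(1, 0, 0))
  M <- rbind(fr$zeta, fr$eta, fr$xi)
  expect_equal(M %*% t(M), diag(3), tolerance = 1e-12)
  # n at 45 degrees in the xy-plane: z-hat is already orthogonal
  fr45 <- local_frame(c(1, 1, 0) / sqrt(2))
  expect_equal(fr45$zeta, c(0, 0, 1))
  expect_equal(det(rbind(fr45$zeta, fr45$eta, fr45$xi)), 1, tolerance = 1e-12)
  expect_error(local_frame(c(0, 0, 1)), "parallel")
})

test_that("exact ellipse points are recovered to high accuracy", {
  th <- seq(0, 2 * pi, length.out = 73)[-1]
  h <- 2; w <- 1; ang <- 30 * pi / 180
  X0 <- h * cos(th); Y0 <- w * sin(th)
  X <- X0 * cos(ang) - Y0 * sin(ang) + 0.3
  Y <- X0 * sin(ang) + Y0 * cos(ang) - 0.1
  f <- fit_ellipse(X, Y)
  expect_equal(sort(c(f$h, f$w)), c(1, 2), tolerance = 1e-6)
  expect_equal(f$center, c(0.3, -0.1), tolerance = 1e-6)
  expect_lt(f$rms, 1e-8)
  expect_null(fit_ellipse(X[1:5], Y[1:5]))   # too few points
})

test_that("cross-section metrics pass construct-and-recover on tori", {
  g <- grid_create(c(64, 64, 64), c(1, 1, 1))
  frame <- local_frame(c(1, 0, 0))
  ctr <- c(.5, .5, .5)
  iso <- isosurface(torus_field(g), g, level = 0)
  ell <- cross_section_ellipses(iso, frame, ctr)
  for (nm in c("forward", "back", "right", "left")) {
    expect_false(is.null(ell[[nm]]))
    expect_equal(ell[[nm]]$aspect, 1, tolerance = 0.02)
  }
  # tube cross-sections squashed 2:1 along the axis direction
  iso_sq <- isosurface(torus_field(g, squash_x = 0.5), g, level = 0)
  ell_sq <- cross_section_ellipses(iso_sq, frame, ctr)
  for (nm in c("forward", "back", "right", "left")) {
    expect_equal(ell_sq[[nm]]$aspect, 0.5, tolerance = 0.03 * 2)
  }
})

test_that("bending angles fold to deviation from collinearity with xi sign", {
  frame <- local_frame(c(1, 0, 0))
  ctr <- c(0, 0, 0)
  mk <- function(split, xi) list(center = c(split, xi), h = 1, w = 1,
                                 theta = 0, aspect = 1, rms = 0)
  # collinear opposite centers: zero angle
  e0 <- list(forward = mk(0.3, 0), back = mk(-0.3, 0),
             right = mk(0.3, 0), left = mk(-0.3, 0))
  b0 <- bending_angles(e0, ctr, frame)
  expect_equal(b0$meridian, 0)
  # displaced +0.1 along xi with arms 0.3: 2 atan(1/3), positive
  e1 <- list(forward = mk(0.3, 0.1), back = mk(-0.3, 0.1),
             right = mk(0.3, -0.1), left = mk(-0.3, -0.1))
  b1 <- bending_angles(e1, ctr, frame)
  expect_equal(b1$meridian, 2 * atan(0.1 / 0.3) * 180 / pi, tolerance = 1e-10)
  expect_equal(b1$prime_vertical, -b1$meridian)   # mirror image: sign flips
  # missing center propagates as missing metric
  e2 <- e1; e2$back <- NULL
  expect_true(is.na(bending_angles(e2, ctr, frame)$meridian))
})

test_that("projected-circle ratios respond to elongation and topology", {
  g <- grid_create(c(64, 64, 64), c(1, 1, 1))
  frame <- local_frame(c(1, 0, 0))
  ctr <- c(.5, .5, .5)
  iso <- isosurface(torus_field(g), g, level = 0)
  pr <- projected_circle_ratios(iso, frame, ctr)
  expect_equal(pr$inner, 1, tolerance = 0.02)
  expect_equal(pr$outer, 1, tolerance = 0.02)
  # stretched 1.5x along eta: both outlines become 1/1.5 ellipses
  # (smaller torus so the stretched shape stays inside the unit box)
  iso_el <- isosurface(torus_field(g, r = 0.08, R = 0.24, scale_eta = 1.5),
                       g, level = 0)
  pr_el <- projected_circle_ratios(iso_el, frame, ctr)
  expect_equal(pr_el$inner, 1 / 1.5, tolerance = 0.03 * 1.5)
  expect_equal(pr_el$outer, 1 / 1.5, tolerance = 0.03 * 1.5)
  # a sphere has no hole: inner outline missing, outer round
  fs <- array(0, dim = g$n)
  x <- grid_centers(g, 1)
  for (k in 1:64) fs[, , k] <- sqrt(outer((x - .5)^2, (x - .5)^2, `+`) +
                                      (x[k] - .5)^2) - 0.3
  iso_s <- isosurface(fs, g, level = 0)
  pr_s <- projected_circle_ratios(iso_s, frame, ctr)
  expect_true(is.na(pr_s$inner))
  expect_equal(pr_s$outer, 1, tolerance = 0.02)
})

test_that("metrics are invariant under translation and scaling", {
  g <- grid_create(c(64, 64, 64), c(1, 1, 1))
  frame <- local_frame(c(1, 0, 0))
  iso <- isosurface(torus_field(g, r = 0.08, R = 0.24, scale_eta = 1.3),
                    g, level = 0)
  ctr <- c(.5, .5, .5)
  e1 <- cross_section_ellipses(iso, frame, ctr)
  iso_t <- iso; iso_t$vertices <- sweep(iso$vertices, 2, c(1, -2, 0.5), `+`)
  e2 <- cross_section_ellipses(iso_t, frame, ctr + c(1, -2, 0.5))
  expect_equal(e1$forward$aspect, e2$forward$aspect, tolerance = 1e-6)
  iso_s <- iso; iso_s$vertices <- sweep(iso$vertices, 2, ctr) * 2
  iso_s$vertices <- sweep(iso_s$vertices, 2, ctr, `+`)
  e3 <- cross_section_ellipses(iso_s, frame, ctr)
  # scaling: limited by the fit's relative stopping tolerance
  expect_equal(e1$forward$aspect, e3$forward$aspect, tolerance = 1e-4)
})

test_that("moving averages truncate at edges and spectra find the tone", {
  expect_equal(moving_average(rep(2, 5), 3), rep(2, 5))
  expect_equal(moving_average(c(0, 3, 0, 3, 0), 3), c(1.5, 1, 2, 1, 1.5))
  expect_error(moving_average(1:5, 0), "window")
  t <- seq(0, 10 - 0.01, by = 0.01)
  s <- sin(2 * pi * 3 * t)
  sp <- spectrum_series(s, 0.01)
  expect_equal(sp$frequency[which.max(sp$amplitude)], 3, tolerance = 0.11)
})
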