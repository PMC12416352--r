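test_that("the cavity starts at the published solid position and conserves it", {
  r <- run_cavity(n = 24, t_end = 0.3, record_every = 2L,
                  snapshot_times = numeric(0), n_tracers = 16L)
  s <- r$series
  expect_equal(c(s$xc[1], s$yc[1]), c(0.6, 0.5), tolerance = 2e-3)
  expect_lt(abs(tail(s$solid_volume, 1) / s$solid_volume[1] - 1), 1e-12)
  expect_lt(max(s$max_div), 1e-8)
  expect_equal(nrow(r$tracers), 16)   # tracer count is conserved
  expect_gt(length(r$contour), 0)
})

test_that("a near-rigid solid translates without shedding area", {
  # large shear modulus: the disk must circulate with little deformation
  r <- run_cavity(n = 32, t_end = 1.5, G = 50, record_every = 5L,
                  snapshot_times = numeric(0), n_tracers = 0L)
  expect_false(r$diverged)
  s <- r$series
  expect_lt(abs(tail(s$solid_volume, 1) / s$solid_volume[1] - 1), 0.01)
  # area-equivalent radius change below 1%
  r_eq <- sqrt(s$solid_volume / pi)
  expect_lt(max(abs(r_eq / r_eq[1] - 1)), 0.01)
  # and it has moved with the vortex
  expect_gt(abs(tail(s$xc, 1) - 0.6) + abs(tail(s$yc, 1) - 0.5), 0.05)
})

test_that("a stopped run resumes bit-identically from its state", {
  r0 <- run_cavity(n = 24, t_end = 0, record_every = 1L,
                   snapshot_times = numeric(0), n_tracers = 9L)
  opts <- c(list(co = 0.1, nu_f = 0.01, nu_s = 0.01, G = 0.05,
                 reset_unit = FALSE, n_outer = 2L, poisson_kind = 0L,
                 record_every = 0L, track_shape = FALSE, solid_on = TRUE),
            eulfsi:::vel_bc_matrices(r0$grid, lid = c(1, 0, 0)))
  full <- fsi_run(r0$grid, r0$state, c(opts, nsteps = 40L))
  half <- fsi_run(r0$grid, r0$state, c(opts, nsteps = 20L))
  tf <- tempfile(fileext = ".rds")
  write_checkpoint(list(grid = r0$grid, state = half$state, config = NULL), tf)
  ck <- read_checkpoint(tf)
  rest <- fsi_run(ck$grid, ck$state, c(opts, nsteps = 20L))
  expect_identical(rest$state$alpha, full$state$alpha)
  expect_identical(rest$state$u, full$state$u)
  expect_identical(rest$state$btilde, full$state$btilde)
  expect_identical(rest$state$tracers, full$state$tracers)
  expect_identical(rest$state$t, full$state$t)
  unlink(tf)
})

test_that("config files round-trip, convert units, and reject bad input", {
  tf <- tempfile(fileext = ".yaml")
  writeLines(c(
    "case: torus_in_pipe",
    "re: 50",
    "solid:",
    "  G_pa: 100",
    "  viscosity_ratio: 2",
    "particle:",
    "  shape: torus",
    "  r: 0.1",
    "  R: 0.3",
    "  psi0: 45",
    "numerics:",
    "  grid: [48, 16, 16]",
    "  length: [3, 1, 1]",
    "seed: 4"), tf)
  cfg <- load_config(tf)
  expect_equal(cfg$G, 10)               # 100 Pa / (rho U^2 = 10 Pa)
  expect_equal(cfg$nu_f, 0.01)          # 1 / (2 Re)
  expect_equal(cfg$nu_s, 0.02)
  expect_equal(cfg$target_mean, 0.5)
  expect_equal(cfg$particle$psi0, 45)
  expect_identical(config_hash(cfg), config_hash(load_config(tf)))
  writeLines(c("case: cavity", "bogus_key: 1"), tf)
  expect_error(load_config(tf), "unknown config key")
  # inconsistent Re vs dimensional viscosity: the tables disagree; pin Re
  writeLines(c("case: torus_in_pipe", "re: 50", "solid:",
               "  mu_f_pa_s: 1.0e-5"), tf)
  expect_error(load_config(tf), "pin")
  expect_error(case_config(G_pa = -5), "non-negative")
  unlink(tf)
})

test_that("field snapshots and surfaces write to standard formats", {
  g <- grid_create(c(8, 8, 8), c(1, 1, 1))
  a <- rasterize(particle_spec("sphere", rs = 0.25, center = c(.5, .5, .5)), g)
  u <- vector_field(g); u$x[] <- 1
  tf <- tempfile(fileext = ".vti")
  write_vti(list(alpha = a, U = u), g, tf)
  txt <- readLines(tf)
  expect_true(any(grepl("VTKFile type=\"ImageData\"", txt)))
  expect_true(any(grepl("Name=\"alpha\"", txt)))
  expect_true(any(grepl("NumberOfComponents=\"3\"", txt)))
  iso <- isosurface(a, g, 0.5)
  ts <- tempfile(fileext = ".stl")
  write_stl(iso, ts)
  stl <- readLines(ts)
  expect_true(grepl("^solid", stl[1]))
  expect_equal(sum(grepl("facet normal", stl)), nrow(iso$triangles))
  # missing metrics become empty CSV cells, not zeros
  tc <- tempfile(fileext = ".csv")
  write_series(data.frame(t = 1, psi = NA_real_), tc)
  expect_true(grepl(",$", readLines(tc)[2]))
  unlink(c(tf, ts, tc))
})

test_that("local maxima detection finds isolated prominent peaks", {
  t <- seq(0, 10, by = 0.05)
  x <- exp(-(t - 3)^2 / 0.2) + 0.7 * exp(-(t - 7)^2 / 0.3)
  pk <- local_maxima(x, smooth = 3)
  expect_length(pk, 2)
  expect_equal(t[pk], c(3, 7), tolerance = 0.1)
  expect_length(local_maxima(rep(1, 50)), 0)
})
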