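# End-to-end scenario drivers: lid-driven cavity FSI verification, forced
# Hagen-Poiseuille pipe, torus transport in a periodic pipe, and the
# stenotic-pipe embolization test, plus the grid-convergence study.

#' Low-level coupled time stepper
#'
#' Advances a full state (volume fraction, staggered velocity, pressure,
#' deformation tensor, forcing accumulator, interface normals) by the
#' compiled solver loop. Scenario drivers build on this; it is exported so
#' runs can be checkpointed and resumed: feeding the returned `state` back
#' in continues the simulation bit-identically.
#'
#' @param grid an `fsi_grid`.
#' @param state a state list (see [write_checkpoint()]); scenario results
#'   carry one in `$state`.
#' @param opts named list of solver options (physics, BCs, cadences) as
#'   assembled by the scenario drivers.
#' @return list with updated `state`, the diagnostics `series` data frame,
#'   `snapshots`, and divergence flags.
#' @export
fsi_run <- function(grid, state, opts) run_core(grid, state, opts)

# internal: assemble options and run the compiled coupled stepper
run_core <- function(grid, state, opts) {
  out <- cpp_fsi_run(grid_for_cpp(grid), state, opts)
  series <- as.data.frame(out$series)
  list(grid = grid, state = out$state, series = series,
       snapshots = out$snapshots, diverged = isTRUE(out$diverged),
       error = out$error, steps = out$steps)
}

# initial combined state for the compiled core
init_state <- function(grid, alpha = NULL, btilde = NULL, u = NULL,
                       tracers = NULL) {
  if (is.null(alpha)) alpha <- scalar_field(grid)
  if (is.null(u)) u <- vector_field(grid)
  if (is.null(btilde)) btilde <- sym_tensor_field(grid, diag_value = 1)
  list(alpha = as.numeric(alpha), u = lapply(u, as.numeric),
       p = as.numeric(scalar_field(grid)),
       btilde = btilde_to_cpp(btilde, grid),
       t = 0, S = 0, step = 0,
       plic_normals = NULL,
       tracers = tracers)
}

#' Lid-driven cavity with a visco-hyperelastic disk
#'
#' The verification case: a unit square cavity, lid moving with
#' `u_x = 1`, and a Neo-Hookean solid disk of radius 0.2 centered at
#' (0.6, 0.5) with `rho = 1`, `mu_s = mu_f = 0.01` and `G = 0.05`. The
#' deformation tensor starts from `sqrt(alpha) I` and clipped cells reset
#' to the zero tensor. Returns the centroid trajectory, solid contour
#' (alpha = 0.5 isoline), Lagrangian tracers and field snapshots.
#'
#' @param n grid cells per side.
#' @param t_end dimensionless end time (lid velocity = cavity side = 1).
#' @param G,mu shear modulus and (equal) fluid/solid viscosity.
#' @param radius,center solid disk geometry.
#' @param co Courant limit.
#' @param n_outer outer correctors.
#' @param record_every series cadence in steps.
#' @param snapshot_times times at which full field snapshots are kept.
#' @param n_tracers Lagrangian markers seeded on a grid inside the solid.
#' @return `scenario_result` list: `series` (t, centroid, volumes...),
#'   `contour` (final alpha=0.5 isolines), `tracers`, `snapshots`,
#'   `state`, `grid`, `diverged`.
#' @export
run_cavity <- function(n = 64, t_end = 20, G = 0.05, mu = 0.01,
                       radius = 0.2, center = c(0.6, 0.5), co = 0.1,
                       n_outer = 2L, record_every = 4L,
                       snapshot_times = c(4, 8), n_tracers = 81L) {
  grid <- grid_create(c(n, n), c(1, 1))
  spec <- particle_spec("sphere", rs = radius, center = c(center, 0))
  alpha <- rasterize(spec, grid)
  btilde <- sym_tensor_field(grid)
  for (cn in c("xx", "yy", "zz")) btilde[[cn]] <- sqrt(alpha)
  tracers <- NULL
  if (n_tracers > 0) {
    side <- ceiling(sqrt(2 * n_tracers)) + 1L
    gx <- seq(-radius, radius, length.out = side)
    pts <- as.matrix(expand.grid(x = gx, y = gx))
    pts <- pts[rowSums(pts^2) <= radius^2 * 0.92, , drop = FALSE]
    pts <- pts[seq_len(min(nrow(pts), n_tracers)), , drop = FALSE]
    tracers <- cbind(pts[, 1] + center[1], pts[, 2] + center[2], 0)
  }
  bcm <- vel_bc_matrices(grid, lid = c(1, 0, 0))
  dt_ref <- min(co * grid$dx, grid$dx^2 / (8 * mu))
  snap_every <- if (length(snapshot_times))
    max(1L, as.integer(round(min(diff(c(0, sort(snapshot_times)))) / dt_ref)))
  else 0L
  opts <- c(list(co = co, nu_f = mu, nu_s = mu, G = G,
                 alpha_min = 0.1, reset_unit = FALSE,
                 zero_alpha_clip = FALSE,
                 solid_on = TRUE, n_outer = as.integer(n_outer),
                 forcing_on = FALSE, poisson_kind = 0L,
                 record_every = as.integer(record_every),
                 snapshot_every = snap_every,
                 t_end = t_end, track_shape = TRUE), bcm)
  res <- run_core(grid, init_state(grid, alpha, btilde, tracers = tracers),
                  opts)
  af <- array(res$state$alpha, dim = grid$n)
  res$contour <- alpha_contour(af, grid)
  res$tracers <- res$state$tracers
  res$config <- list(n = n, t_end = t_end, G = G, mu = mu, radius = radius,
                     center = center, co = co)
  class(res) <- "scenario_result"
  res
}

# alpha = 0.5 isolines of a 2D field
alpha_contour <- function(alpha, grid, level = 0.5) {
  grDevices::contourLines(x = grid_centers(grid, 1), y = grid_centers(grid, 2),
                          z = alpha, levels = level)
}

#' Forced Hagen-Poiseuille pipe flow verification
#'
#' Integrates the axisymmetric reduction of the periodic pipe from rest
#' with the mean-flow forcing controller, to steady state, and evaluates
#' the L2 error of the axial velocity along a diameter against the
#' analytic profile `u_x(y) = 8 ubar y (1 - y)`.
#'
#' @param nr radial intervals (cells across the diameter = `2 nr`).
#' @param re Reynolds number.
#' @param target_mean dimensionless bulk velocity (0.5).
#' @param co Courant limit.
#' @return `scenario_result` with the steady `profile`, `l2` error,
#'   steady forcing `S` (and its analytic value), and the forcing series.
#' @export
run_poiseuille <- function(nr = 32L, re = 50, target_mean = 0.5, co = 0.1) {
  res <- axisym_pipe_flow(nr = nr, re = re, target_mean = target_mean,
                          co = co)
  out <- list(profile = data.frame(y = res$y, ux = res$ux,
                                   ux_exact = res$ux_exact),
              l2 = res$l2, S = res$S, S_exact = res$S_exact,
              mean_velocity = res$mean_velocity, steps = res$steps,
              series = data.frame(S = res$s_series,
                                  mean_velocity = res$mean_series),
              config = list(nr = nr, re = re, target_mean = target_mean))
  class(out) <- "scenario_result"
  out
}

# build the periodic-pipe initial state for a particle case
pipe_setup <- function(config) {
  n <- config$n
  len <- config$length
  grid <- grid_create(n, len, periodic = c(TRUE, FALSE, FALSE),
                      wall_mask = NULL)
  wall <- pipe_mask(grid_create(n, len, periodic = c(TRUE, FALSE, FALSE)),
                    radius = 0.5)
  grid <- grid_create(n, len, periodic = c(TRUE, FALSE, FALSE),
                      wall_mask = wall)
  spec <- config$particle
  if (is.null(spec)) {
    spec <- particle_spec("torus", r = 0.1, R = 0.3,
                          center = c(len[1] / 2, 0.5, 0.5), psi0 = 45)
  }
  alpha <- rasterize(spec, grid)
  btilde <- sym_tensor_field(grid, diag_value = 1)
  u <- vector_field(grid)
  if (config$perturb_amplitude > 0) {
    set.seed(config$seed)
    u$x <- array(config$perturb_amplitude *
                   stats::runif(length(u$x), -1, 1), dim = dim(u$x))
  }
  list(grid = grid, alpha = alpha, btilde = btilde, u = u, spec = spec)
}

#' Deformable torus transported in a periodic pipe
#'
#' The main transport scenario: a Neo-Hookean torus in a periodic
#' cylindrical pipe (stair-step wall mask) driven by the mean-flow
#' forcing controller at bulk velocity 0.5. The orientation angle,
#' centroid, forcing (pressure-gradient readout) and solid volume are
#' recorded continuously; full snapshots at the requested cadence feed
#' the cross-section deformation metrics.
#'
#' @param config a [case_config()]; `config$particle` positions/orients
#'   the torus (default: `r = 0.1`, `R = 0.3`, centered, `psi0 = 45`).
#' @param metrics compute [shape_metrics()] on the stored snapshots.
#' @return `scenario_result` with `series` (ψ(t), centroid, S, ...),
#'   `metrics` (per-snapshot deformation table), `snapshots`, final
#'   `state`.
#' @export
run_torus_in_pipe <- function(config = case_config(), metrics = TRUE) {
  setup <- pipe_setup(config)
  grid <- setup$grid
  opts <- c(list(co = config$co, nu_f = config$nu_f, nu_s = config$nu_s,
                 G = config$G, alpha_min = config$alpha_min,
                 reset_unit = config$reset == "unit",
                 zero_alpha_clip = FALSE,
                 solid_on = TRUE, n_outer = config$n_outer,
                 rdf_iters = config$rdf_iters,
                 forcing_on = TRUE, target_mean = config$target_mean,
                 poisson_kind = 0L,
                 record_every = config$record_every,
                 snapshot_every = config$snapshot_every,
                 t_end = config$t_end, track_shape = TRUE),
            vel_bc_matrices(grid))
  res <- run_core(grid, init_state(grid, setup$alpha, setup$btilde,
                                   u = setup$u), opts)
  res$config <- config
  res$particle <- setup$spec
  if (metrics && length(res$snapshots)) {
    rows <- list()
    prev_n <- NULL
    for (s in seq_along(res$snapshots)) {
      sn <- res$snapshots[[s]]
      m <- try(shape_metrics(array(sn$alpha, dim = grid$n), sn$u, grid,
                             t = sn$t, prev_n = prev_n), silent = TRUE)
      if (!inherits(m, "try-error")) {
        prev_n <- m$n
        rows[[length(rows) + 1]] <- metrics_row(m)
      }
    }
    res$metrics <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  class(res) <- "scenario_result"
  res
}

#' Embolization test: particle transport through a stenotic pipe
#'
#' Pressure-driven flow (alternative pressure fixed at 5.5 at the inlet
#' and 0 at the outlet, velocity zero-gradient at both ends) through an
#' axisymmetric stenosis; the particle starts near the inlet, inclined at
#' 45 degrees and offset 0.5 from the axis. Records the inlet-outlet
#' pressure difference (measured between the first and last cell planes)
#' and the outlet flow rate. Solver divergence is reported as series
#' truncation (`diverged = TRUE`), not as an error: the non-torus shapes
#' are expected to diverge under the pressure spike at wall contact.
#'
#' @param config a [case_config()] (use `n`, `length = c(6, 2, 2)`);
#'   `config$particle` defaults to the reference torus.
#' @param inlet_radius,throat_radius stenosis geometry.
#' @param p_in,p_out dimensionless boundary pressures.
#' @param baseline run without a particle.
#' @return `scenario_result` with `series` (`dp`, `q_out`, ...),
#'   `diverged`, `t_diverged`.
#' @export
run_stenosis <- function(config = case_config(case = "stenosis",
                                              n = c(96, 32, 32),
                                              length = c(6, 2, 2),
                                              t_end = 8),
                         inlet_radius = 1, throat_radius = 0.5,
                         p_in = 5.5, p_out = 0, baseline = FALSE) {
  n <- config$n
  len <- config$length
  g0 <- grid_create(n, len)
  wall <- stenosis_mask(g0, length = len[1], inlet_radius = inlet_radius,
                        throat_radius = throat_radius)
  grid <- grid_create(n, len, wall_mask = wall)
  spec <- config$particle
  if (is.null(spec) && !baseline) {
    spec <- particle_spec("torus", r = 0.1, R = 0.3,
                          center = c(0.7, len[2] / 2 - 0.5, len[3] / 2),
                          psi0 = 45)
  }
  alpha <- if (baseline || is.null(spec)) scalar_field(grid) else
    rasterize(spec, grid)
  btilde <- sym_tensor_field(grid, diag_value = 1)
  opts <- c(list(co = config$co, nu_f = config$nu_f, nu_s = config$nu_s,
                 G = config$G, alpha_min = config$alpha_min,
                 reset_unit = TRUE, zero_alpha_clip = FALSE,
                 solid_on = !baseline && !is.null(spec),
                 n_outer = config$n_outer, rdf_iters = config$rdf_iters,
                 forcing_on = FALSE, poisson_kind = 1L,
                 dir_xlo = TRUE, dir_xhi = TRUE,
                 p_xlo = p_in, p_xhi = p_out,
                 record_every = config$record_every,
                 snapshot_every = config$snapshot_every,
                 t_end = config$t_end, track_shape = !baseline),
            vel_bc_matrices(grid, open_x = TRUE))
  res <- run_core(grid, init_state(grid, alpha, btilde), opts)
  res$config <- config
  res$particle <- spec
  res$t_diverged <- if (res$diverged) max(res$series$t) else NA_real_
  class(res) <- "scenario_result"
  res
}

#' Run the four surface-area-matched shapes through the stenosis
#'
#' Builds the published same-area shape set (reference torus, disk with
#' `rd = 2 h`, sphere, ellipsoid with long axis 0.4) and runs each through
#' the stenotic pipe with identical initial placement (inclined 45 degrees,
#' offset 0.5 from the axis, near the inlet). Each result gains a `peaks`
#' field with the indices of the prominent local maxima of the measured
#' pressure-difference series.
#'
#' @param n grid cells per axis.
#' @param t_end dimensionless horizon per run.
#' @param record_every series cadence.
#' @param ... forwarded to [run_stenosis()].
#' @return named list of `scenario_result`s
#'   (`torus`, `disk`, `sphere`, `ellipsoid`).
#' @export
stenosis_shape_set <- function(n = c(72, 24, 24), t_end = 6,
                               record_every = 10L, ...) {
  ref <- particle_spec("torus", r = 0.1, R = 0.3)
  len <- c(6, 2, 2)
  center <- c(0.7, len[2] / 2 - 0.5, len[3] / 2)
  shapes <- list(
    torus = particle_spec("torus", r = 0.1, R = 0.3, center = center,
                          psi0 = 45),
    disk = match_area(ref, "disk", center = center, psi0 = 45),
    sphere = match_area(ref, "sphere", center = center, psi0 = 45),
    ellipsoid = match_area(ref, "ellipsoid", center = center, psi0 = 45))
  cfg0 <- case_config(case = "stenosis", n = n, length = len,
                      t_end = t_end, record_every = record_every)
  base <- run_stenosis(cfg0, baseline = TRUE, ...)
  bres <- base$series$dp / pmax(base$series$q_out, 1e-6)
  out <- lapply(shapes, function(sp) {
    cfg <- case_config(case = "stenosis", n = n, length = len,
                       t_end = t_end, particle = sp,
                       record_every = record_every)
    r <- run_stenosis(cfg, ...)
    # passage signature: prominent maxima of the smoothed pressure
    # difference after the flow has developed (t >= 1.5)
    sub <- which(r$series$t >= 1.5)
    pk <- local_maxima(r$series$dp[sub], smooth = 9, min_prominence = 0.15)
    r$peaks <- sub[pk]
    r$peak_dp <- if (length(sub)) max(r$series$dp[sub]) else NA_real_
    # blockage burden relative to the particle-free baseline: with both end
    # pressures pinned the raw pressure difference is nearly clamped, so
    # the ranking observable is the hydraulic resistance dp / Q
    nshare <- min(nrow(r$series), length(bres))
    resis <- r$series$dp[1:nshare] / pmax(r$series$q_out[1:nshare], 1e-6) -
      bres[1:nshare]
    w <- which(r$series$t[1:nshare] >= 1.5)
    r$peak_resistance <- if (length(w)) max(resis[w]) else NA_real_
    qred <- (base$series$q_out[1:nshare] - r$series$q_out[1:nshare]) /
      pmax(base$series$q_out[1:nshare], 1e-6)
    r$peak_flow_reduction <- if (length(w)) max(qred[w]) else NA_real_
    r
  })
  attr(out, "baseline") <- base
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>")
  if (!is.null(x$series)) cat(sprintf(" %d series rows", nrow(x$series)))
  if (!is.null(x$l2)) cat(sprintf(" l2 = %.3g", x$l2))
  if (isTRUE(x$diverged)) cat(sprintf(" [diverged at t = %.3g]", max(x$series$t)))
  cat("\n")
  invisible(x)
}

#' Local maxima of a (possibly noisy) series
#'
#' Peaks above a prominence floor after optional smoothing; used for the
#' stenosis pressure-drop passage signature.
#'
#' @param x numeric series.
#' @param smooth moving-average window applied first (1 = none).
#' @param min_prominence required drop on both sides, as a fraction of the
#'   series range.
#' @return integer indices of the local maxima.
#' @export
local_maxima <- function(x, smooth = 1L, min_prominence = 0.05) {
  if (smooth > 1) x <- moving_average(x, smooth)
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(cand)) return(integer(0))
  rng <- diff(range(x))
  if (rng <= 0) return(integer(0))
  keep <- vapply(cand, function(i) {
    left <- min(x[1:i]); right <- min(x[i:n])
    (x[i] - max(left, right)) / rng >= min_prominence
  }, logical(1))
  cand[keep]
}

#' Grid-convergence study of the cavity centroid trajectory
#'
#' Runs the cavity FSI case at several resolutions, interpolates the
#' centroid trajectories onto a common time grid, and reports the L2 and
#' L-infinity trajectory errors against the finest grid together with the
#' fitted convergence order.
#'
#' @param resolutions coarse grid sizes (>= 2 values).
#' @param reference finest grid size (the reference trajectory).
#' @param t_end horizon for every run.
#' @param dt_sample common sampling interval for the error norms.
#' @param ... forwarded to [run_cavity()].
#' @return list with the error `table`, fitted `order_l2` / `order_linf`,
#'   and the runs' sampled trajectories.
#' @export
convergence_study <- function(resolutions = c(16, 32, 64), reference = 128,
                              t_end = 20, dt_sample = 0.1, ...) {
  stopifnot(length(resolutions) >= 2)
  tgrid <- seq(dt_sample, t_end - dt_sample, by = dt_sample)
  sample_traj <- function(n) {
    r <- run_cavity(n = n, t_end = t_end, ...)
    if (r$diverged) stop("cavity run diverged at n = ", n)
    s <- r$series
    cbind(x = stats::approx(s$t, s$xc, tgrid)$y,
          y = stats::approx(s$t, s$yc, tgrid)$y)
  }
  ref <- sample_traj(reference)
  tab <- data.frame(n = integer(0), l2 = numeric(0), linf = numeric(0))
  trajs <- list()
  for (n in resolutions) {
    tr <- sample_traj(n)
    d <- sqrt(rowSums((tr - ref)^2))
    tab <- rbind(tab, data.frame(n = n, l2 = sqrt(mean(d^2)), linf = max(d)))
    trajs[[as.character(n)]] <- tr
  }
  fit <- function(err) {
    -stats::coef(stats::lm(log(err) ~ log(tab$n)))[[2]]
  }
  list(table = tab, order_l2 = fit(tab$l2), order_linf = fit(tab$linf),
       trajectories = trajs, reference = ref, t = tgrid)
}
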