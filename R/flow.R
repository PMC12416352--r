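# One-field momentum equation with pressure projection and the mean-flow
# forcing controller.

#' Create a flow state
#'
#' Bundles the staggered velocity, the alternative pressure `p_rgh`, the
#' uniform forcing source `S` (flow-direction component), the simulation
#' clock and the step counter.
#'
#' @param grid the `fsi_grid`.
#' @param u optional initial staggered velocity (default rest).
#' @return object of class `flow_state`.
#' @export
flow_state <- function(grid, u = NULL) {
  if (is.null(u)) u <- vector_field(grid)
  structure(list(u = u, p = scalar_field(grid), S = 0,
                 t = 0, step = 0L, poisson_residual = NA_real_),
            class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("<flow_state> t = %.4g, step %d, S = %.4g\n", x$t, x$step, x$S))
  invisible(x)
}

#' Stable time-step size
#'
#' The minimum of the convective Courant bound, the viscous bound
#' `dx^2 / (3 nu)` and the elastic-wave bound `dx / sqrt(G / rho)`.
#' The coupled stepping loop uses stricter safety factors internally
#' (`dx^2 / (12 nu)` and `0.5 dx / sqrt(G)`, both terms being integrated
#' explicitly there) — this function exposes the stability-condition
#' contract itself.
#'
#' @param umax current maximum velocity magnitude.
#' @param dx grid spacing.
#' @param co Courant number limit.
#' @param nu_max largest kinematic viscosity in the domain.
#' @param G dimensionless shear modulus (0 for pure fluid).
#' @param rho density (1 in dimensionless form).
#' @return time step.
#' @export
compute_dt <- function(umax, dx, co = 0.1, nu_max = 0, G = 0, rho = 1) {
  dt <- co * dx / max(umax, 1e-12)
  if (nu_max > 0) dt <- min(dt, dx^2 / (3 * nu_max))
  if (G > 0) dt <- min(dt, dx / sqrt(G / rho))
  if (dt < 1e-10) stop("time step collapsed below 1e-10")
  dt
}

# assemble the state list the compiled core expects
state_for_cpp <- function(grid, flow, alpha = NULL, btilde = NULL) {
  if (is.null(alpha)) alpha <- scalar_field(grid)
  if (is.null(btilde)) btilde <- sym_tensor_field(grid, diag_value = 1)
  list(alpha = as.numeric(alpha),
       u = lapply(flow$u, as.numeric),
       p = as.numeric(flow$p),
       btilde = btilde_to_cpp(btilde, grid),
       t = flow$t, S = flow$S, step = as.numeric(flow$step),
       plic_normals = attr(alpha, "plic_normals"))
}

state_from_cpp <- function(st, grid, flow) {
  flow$u <- st$u
  flow$p <- array(st$p, dim = grid$n)
  flow$t <- st$t
  flow$S <- st$S
  flow$step <- as.integer(st$step)
  flow
}

# velocity BC encoding: kinds 0 periodic / 1 wall / 2 open, per axis lo/hi
vel_bc_matrices <- function(grid, open_x = FALSE, lid = NULL) {
  kind <- matrix(1L, 3, 2)
  for (d in seq_len(grid$ndim)) if (grid$periodic[d]) kind[d, ] <- 0L
  if (grid$ndim == 2L) kind[3, ] <- 0L
  if (open_x) kind[1, ] <- 2L
  tang <- matrix(0, 6, 3)
  if (!is.null(lid)) tang[4, ] <- lid  # y-hi patch tangential velocity
  list(vel_kind = kind, vel_tang = tang)
}

#' One momentum step (predictor + pressure projection)
#'
#' Explicit predictor (limited second-order upwind advection, conservative
#' variable-viscosity stress, elastic force, uniform source), then an
#' incompressibility projection on the staggered grid; outer correctors
#' re-evaluate the explicit terms from the corrected velocity. The
#' volume fraction and deformation tensor are treated as already advanced
#' for this step (solver ordering: interface advection, then tensor
#' evolution, then momentum).
#'
#' @param flow a [flow_state()].
#' @param btilde deformation tensor field (or `NULL` for pure fluid).
#' @param alpha volume-fraction array (or `NULL`).
#' @param dt time step.
#' @param grid the `fsi_grid`.
#' @param config list of physical/numerical parameters: `nu_f`, `nu_s`,
#'   `G`, `n_outer`, velocity BCs (`open_x`, `lid`), pressure BCs
#'   (`dirichlet_x`, `p_in`, `p_out`), Poisson backend.
#' @return updated [flow_state()]; `poisson_residual` carries the final
#'   max-divergence.
#' @export
momentum_step <- function(flow, btilde = NULL, alpha = NULL, dt, grid,
                          config = list()) {
  cfg <- modifyList(list(nu_f = 0.01, nu_s = 0.01, G = 0, n_outer = 2L,
                         open_x = FALSE, lid = NULL, dirichlet_x = FALSE,
                         p_in = 0, p_out = 0, poisson = NULL), config)
  poisson_kind <- if (!is.null(cfg$poisson)) {
    if (cfg$poisson == "pcg") 1L else 0L
  } else if (cfg$dirichlet_x || wall_varies_x(grid)) 1L else 0L
  bcm <- vel_bc_matrices(grid, open_x = cfg$open_x, lid = cfg$lid)
  opts <- c(list(nsteps = 1L, dt_fixed = dt, solid_on = !is.null(btilde),
                 advect_on = FALSE, evolve_b_on = FALSE,
                 nu_f = cfg$nu_f, nu_s = cfg$nu_s, G = cfg$G,
                 n_outer = as.integer(cfg$n_outer),
                 poisson_kind = poisson_kind,
                 dir_xlo = isTRUE(cfg$dirichlet_x),
                 dir_xhi = isTRUE(cfg$dirichlet_x),
                 p_xlo = cfg$p_in, p_xhi = cfg$p_out,
                 record_every = 1L, track_shape = FALSE), bcm)
  out <- cpp_fsi_run(grid_for_cpp(grid), state_for_cpp(grid, flow, alpha, btilde),
                     opts)
  if (isTRUE(out$diverged)) stop("momentum step failed: ", out$error)
  flow <- state_from_cpp(out$state, grid, flow)
  flow$poisson_residual <- out$series[nrow(out$series), "max_div"]
  flow
}

# does the wall mask vary along x? (decides the Poisson backend)
wall_varies_x <- function(grid) {
  if (!any(grid$wall)) return(FALSE)
  if (grid$ndim == 2L) w <- grid$wall else w <- grid$wall
  ref <- slice_axis(w, 1, 1L)
  for (i in seq_len(grid$n[1])[-1]) {
    if (!identical(as.vector(slice_axis(w, 1, i)), as.vector(ref))) return(TRUE)
  }
  FALSE
}

#' Mean-flow forcing controller
#'
#' After the projection, measures the bulk axial velocity over the fluid
#' cells and adds the uniform pseudo-pressure-gradient increment
#' `dS = (target - mean) / dt` to the axial momentum; the running
#' accumulator `S` is the pressure-gradient readout (pressure drop =
#' `S * L`).
#'
#' @param flow a [flow_state()].
#' @param target_mean target dimensionless bulk velocity (0.5).
#' @param dt time step used for the increment.
#' @param grid the `fsi_grid`.
#' @return updated flow state.
#' @export
mean_flow_forcing <- function(flow, target_mean, dt, grid) {
  fluid <- !grid$wall
  ux <- flow$u$x
  n1 <- grid$n[1]
  lo <- slice_axis(ux, 1, 1:n1)
  hi <- slice_axis(ux, 1, 1L + 1:n1)
  ucc <- 0.5 * (array(lo, dim = grid$n) + array(hi, dim = grid$n))
  ubar <- mean(ucc[fluid])
  dS <- (target_mean - ubar) / dt
  # increment faces with fluid on both sides
  both_fluid <- array(TRUE, dim = dim(ux))
  if (any(grid$wall)) {
    fl <- fluid
    wrap_lo <- if (grid$periodic[1]) slice_axis(fl, 1, c(n1, 1:n1)) else
      slice_axis(fl, 1, c(1L, 1:n1))
    wrap_hi <- if (grid$periodic[1]) slice_axis(fl, 1, c(1:n1, 1L)) else
      slice_axis(fl, 1, c(1:n1, n1))
    both_fluid <- array(wrap_lo & wrap_hi, dim = dim(ux))
  }
  ux[both_fluid] <- ux[both_fluid] + dS * dt
  flow$u$x <- ux
  flow$S <- flow$S + dS
  flow
}
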