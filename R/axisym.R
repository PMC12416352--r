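# Axisymmetric (r,x) reduction of the forced periodic pipe.
#
# For fully developed single-phase pipe flow the axial momentum equation
# reduces to radial diffusion plus the uniform forcing source:
#   du/dt = nu * (1/r) d/dr(r du/dr) + S,
# with u = 0 at the wall and symmetry at the axis (the convective term
# vanishes identically for u = u_x(r) x-hat). The wall is exact here, unlike
# the stair-step cylinder mask of the 3D solver, which is why the
# Hagen-Poiseuille verification uses this reduction.

#' Forced axisymmetric pipe flow to steady state
#'
#' Integrates the radial reduction of the axial momentum equation from rest
#' with the mean-flow forcing controller active: after every step the bulk
#' velocity over the cross-section is measured (Simpson quadrature in
#' `r dr`), the deficit is added as a uniform momentum source, and the source
#' accumulator `S` is the pressure-gradient readout (pressure drop =
#' `S * L`).
#'
#' Radial nodes sit at `r_j = j * dr`, `j = 0..nr` (so `2 * nr` cells across
#' the diameter), with the no-slip value imposed exactly at the wall node.
#'
#' @param nr radial intervals between axis and wall (diameter resolution is
#'   `2 * nr`; `nr` must be even for the Simpson weights).
#' @param re Reynolds number `rho ubar D / mu` (default 50).
#' @param target_mean dimensionless bulk velocity target (default 0.5;
#'   velocity scale is twice the mean velocity).
#' @param co Courant number limit.
#' @param tol steady-state tolerance on `max|du/dt|`.
#' @param max_steps step cap.
#' @return list with the steady profile along a diameter (`y`, `ux`,
#'   `ux_exact`), the bulk velocity `mean_velocity`, the forcing readout `S`
#'   (with its analytic Poiseuille value `S_exact`), the `l2` error of Eq.-(17)
#'   form, and the forcing/mean time series.
#' @export
axisym_pipe_flow <- function(nr = 32L, re = 50, target_mean = 0.5, co = 0.1,
                             tol = 1e-11, max_steps = 500000L) {
  nr <- as.integer(nr)
  stopifnot(nr >= 4L, nr %% 2L == 0L, re > 0)
  R <- 0.5                       # pipe radius, diameter = 1
  nu <- 1 / (2 * re)             # dimensionless kinematic viscosity (U = 2 ubar)
  dr <- R / nr
  r <- (0:nr) * dr
  # Simpson weights for the cross-section mean (2/R^2) * int u r dr
  w <- rep(c(4, 2), length.out = nr - 1L)
  w <- c(1, w, 1) * dr / 3
  wmean <- 2 * w * r / R^2
  u <- numeric(nr + 1L)
  S <- 0
  s_series <- numeric(0); mean_series <- numeric(0)
  j <- 1:(nr - 1L)      # interior nodes (R index j + 1)
  rph <- (j + 0.5) * dr # face radius above node j
  rmh <- (j - 0.5) * dr # face radius below node j
  steps <- 0L
  repeat {
    umax <- max(abs(u), 1e-12)
    dt <- min(co * dr / umax, 0.2 * dr^2 / nu)
    lap <- numeric(nr + 1L)
    lap[1] <- 4 * (u[2] - u[1]) / dr^2
    lap[j + 1L] <- (rph * (u[j + 2L] - u[j + 1L]) -
                    rmh * (u[j + 1L] - u[j])) / ((j * dr) * dr^2)
    du <- dt * (nu * lap + S)
    du[nr + 1L] <- 0
    u <- u + du
    ubar <- sum(wmean * u)
    dS <- (target_mean - ubar) / dt
    kick <- dS * dt
    u[1:nr] <- u[1:nr] + kick
    S <- S + dS
    ubar <- sum(wmean * u)
    steps <- steps + 1L
    if (steps %% 50L == 0L || steps <= 20L) {
      s_series <- c(s_series, S); mean_series <- c(mean_series, ubar)
    }
    if (max(abs(du)) / dt < tol && steps > 10L) break
    if (steps >= max_steps) {
      warning("axisymmetric pipe flow did not reach steady state in ",
              max_steps, " steps")
      break
    }
  }
  # profile along a diameter, y in [0, 1]
  y <- c(0.5 - rev(r), 0.5 + r[-1])
  ux <- c(rev(u), u[-1])
  ux_exact <- 8 * target_mean * y * (1 - y)
  l2 <- sqrt(mean((ux - ux_exact)^2))
  list(y = y, ux = ux, ux_exact = ux_exact,
       mean_velocity = sum(wmean * u), S = S,
       S_exact = 16 / (2 * re) * 2 * target_mean,
       l2 = l2, steps = steps, nu = nu,
       s_series = s_series, mean_series = mean_series)
}
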