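# Neo-Hookean visco-hyperelastic solid: evolution of the corrected left
# Cauchy-Green tensor Btilde = alpha^(1/2) B and its elastic Cauchy stress.

#' Solid material properties
#'
#' @param G shear modulus (dimensionless; see the config conversion for
#'   dimensional Pa inputs).
#' @param mu_s solid viscosity (dimensionless).
#' @param beta volume-fraction correction exponent; incompressibility
#'   requires `beta = 1/2` and the compiled kernels assume it.
#' @param alpha_min minimum volume fraction: cells below it are reset
#'   (must lie in `(0, 0.5)`; default 0.1).
#' @param reset reset tensor for cells dropping below `alpha_min`:
#'   `"unit"` (pipe cases) or `"zero"` (cavity case).
#' @return object of class `solid_props`.
#' @export
solid_props <- function(G, mu_s = 0, beta = 0.5, alpha_min = 0.1,
                        reset = c("unit", "zero")) {
  reset <- match.arg(reset)
  if (G < 0) stop("shear modulus must be non-negative")
  if (beta != 0.5) stop("beta must equal 1/2 (incompressibility requirement)")
  if (alpha_min <= 0 || alpha_min >= 0.5) stop("alpha_min must lie in (0, 0.5)")
  structure(list(G = G, mu_s = mu_s, beta = beta, alpha_min = alpha_min,
                 reset = reset), class = "solid_props")
}

# grid list in the form the compiled core expects
grid_for_cpp <- function(grid) {
  list(dim = grid$n, dx = grid$dx, periodic = grid$periodic,
       wall = if (any(grid$wall)) as.logical(grid$wall) else NULL)
}

# tensor field <-> 6-component list in compiled order (xx, xy, yy, xz, yz, zz)
btilde_to_cpp <- function(b, grid) {
  zero <- as.numeric(scalar_field(grid))
  list(as.numeric(b$xx), as.numeric(b$xy), as.numeric(b$yy),
       if (is.null(b$xz)) zero else as.numeric(b$xz),
       if (is.null(b$yz)) zero else as.numeric(b$yz),
       as.numeric(b$zz))
}

btilde_from_cpp <- function(bl, grid) {
  comps <- tensor_components(grid$ndim)
  out <- sym_tensor_field(grid)
  idx <- c(xx = 1, xy = 2, yy = 3, xz = 4, yz = 5, zz = 6)
  for (cn in comps) out[[cn]] <- array(bl[[idx[[cn]]]], dim = grid$n)
  out
}

#' Evolve the corrected left Cauchy-Green tensor by one time step
#'
#' Transport `dB/dt + div(u B) = L.B + B.L^T` for the corrected tensor:
#' the advection term is discretized componentwise with a third-order WENO
#' upwind reconstruction in flux form, and the stretching source is
#' integrated with trapezoidal (Crank-Nicolson) weighting through one
#' fixed-point corrector pass. Symmetry is preserved by construction (only
#' the six independent components are stored).
#'
#' @param btilde symmetric tensor field (see [sym_tensor_field()]).
#' @param u staggered velocity field.
#' @param grid the `fsi_grid`.
#' @param dt time step (must satisfy the viscous/elastic stability bounds,
#'   see [compute_dt()]).
#' @return the evolved tensor field; attribute `bmax` holds the largest
#'   absolute component (blow-up monitor).
#' @export
evolve_btilde <- function(btilde, u, grid, dt) {
  out <- cpp_evolve_btilde(grid_for_cpp(grid), btilde_to_cpp(btilde, grid),
                           lapply(u, as.numeric), dt)
  if (out$bmax > 1e6) {
    stop("deformation tensor blow-up (max |Btilde| = ", format(out$bmax), ")")
  }
  b <- btilde_from_cpp(out$btilde, grid)
  attr(b, "bmax") <- out$bmax
  b
}

#' Reset the deformation tensor where the solid fraction is too small
#'
#' Cells with `alpha < alpha_min` (strict inequality) have `alpha` set to 0
#' and `Btilde` replaced by the reset tensor (unit or zero, per
#' [solid_props()]). Setting `zero_alpha = FALSE` applies only the tensor
#' reset and leaves the transported volume fraction untouched, which is what
#' the coupled stepping loop uses so the geometric advection stays
#' conservative.
#'
#' @param btilde symmetric tensor field.
#' @param alpha volume-fraction array.
#' @param props a [solid_props()].
#' @param grid the `fsi_grid`.
#' @param zero_alpha also zero `alpha` in clipped cells (default `TRUE`,
#'   the literal rule).
#' @return list with fields `btilde` and `alpha`.
#' @export
clip_btilde <- function(btilde, alpha, props, grid, zero_alpha = TRUE) {
  clip <- alpha < props$alpha_min
  diag_val <- if (props$reset == "unit") 1 else 0
  for (cn in names(btilde)) {
    btilde[[cn]][clip] <- if (cn %in% c("xx", "yy", "zz")) diag_val else 0
  }
  if (zero_alpha) alpha[clip] <- 0
  list(btilde = btilde, alpha = alpha)
}

#' Elastic force of the solid on the momentum equation
#'
#' Conservative (flux-form) divergence of the elastic Cauchy stress,
#' `(1/rho) div( G alpha^(1/2) dev(Btilde) )`, evaluated at velocity faces;
#' identically zero wherever `alpha = 0`.
#'
#' @inheritParams clip_btilde
#' @return staggered vector field of accelerations.
#' @export
elastic_force <- function(btilde, alpha, props, grid) {
  if (props$beta != 0.5) stop("compiled elastic force assumes beta = 1/2")
  out <- cpp_elastic_force(grid_for_cpp(grid), btilde_to_cpp(btilde, grid),
                           as.numeric(alpha), props$G)
  f <- vector_field(grid)
  f$x <- array(out$x, dim = face_dims(grid, 1))
  f$y <- array(out$y, dim = face_dims(grid, 2))
  if (grid$ndim == 3L) f$z <- array(out$z, dim = face_dims(grid, 3))
  f
}
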