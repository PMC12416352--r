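# Discrete differential operators on the staggered grid.
# These R-level operators define the public contract (and are what the tests
# exercise); the compiled solver core uses the same formulas internally.

# index helper: slice an array along axis d at indices idx
slice_axis <- function(a, d, idx) {
  nd <- length(dim(a))
  args <- rep(list(quote(expr = )), nd)
  args[[d]] <- idx
  do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

assign_axis <- function(a, d, idx, value) {
  nd <- length(dim(a))
  args <- rep(list(quote(expr = )), nd)
  args[[d]] <- idx
  do.call(`[<-`, c(list(a), args, list(value = value)))
}

#' Fill ghost layers of a cell-centered scalar field
#'
#' Returns the field padded by one ghost layer per side, filled according to
#' the boundary spec: `periodic` copies the opposite interior plane, `fixed`
#' mirrors about the boundary face so the face value equals the prescribed
#' value, `zerograd` copies the adjacent interior plane. Cells under the
#' grid's wall mask are set to `wall_value` first (if given).
#'
#' @param field cell-centered array of dim `grid$n`.
#' @param spec an [boundary_spec()] object.
#' @param grid the `fsi_grid`.
#' @param wall_value optional value imposed in wall-masked cells.
#' @return array of dim `grid$n + 2` with ghosts filled.
#' @export
apply_bc <- function(field, spec, grid, wall_value = NULL) {
  stopifnot(identical(dim(field), grid$n))
  if (!is.null(wall_value) && any(grid$wall)) field[grid$wall] <- wall_value
  nd <- grid$ndim
  padded <- array(0, dim = grid$n + 2L)
  idx <- lapply(grid$n, function(m) 1L + seq_len(m))
  padded <- do.call(`[<-`, c(list(padded), idx, list(value = field)))
  axes <- c("x", "y", "z")[seq_len(nd)]
  for (d in seq_len(nd)) {
    m <- grid$n[d]
    lo <- spec[[paste0(axes[d], "lo")]]
    hi <- spec[[paste0(axes[d], "hi")]]
    if (is.null(lo) || is.null(hi)) {
      stop("boundary spec incomplete on axis ", axes[d])
    }
    first_int <- slice_axis(padded, d, 2L)
    last_int <- slice_axis(padded, d, m + 1L)
    lo_ghost <- switch(lo$kind,
      periodic = last_int,
      zerograd = first_int,
      fixed = 2 * lo$value - first_int)
    hi_ghost <- switch(hi$kind,
      periodic = first_int,
      zerograd = last_int,
      fixed = 2 * hi$value - last_int)
    padded <- assign_axis(padded, d, 1L, lo_ghost)
    padded <- assign_axis(padded, d, m + 2L, hi_ghost)
  }
  padded
}

#' Gradient of a cell-centered scalar, evaluated on faces
#'
#' Component `d` lives on faces normal to axis `d`: interior faces use the
#' compact two-point difference (second order on the uniform grid); boundary
#' faces of non-periodic axes use the ghost value implied by the boundary
#' condition, which reduces to a one-sided difference.
#'
#' @inheritParams apply_bc
#' @return staggered vector field (see [vector_field()]).
#' @export
gradient <- function(field, grid, spec = default_bc(grid)) {
  p <- apply_bc(field, spec, grid)
  dx <- grid$dx
  out <- vector_field(grid)
  for (d in seq_len(grid$ndim)) {
    m <- grid$n[d]
    hi <- slice_axis(p, d, 1L + (1:(m + 1L)))   # cells 1..m plus hi ghost
    lo <- slice_axis(p, d, 1:(m + 1L))          # lo ghost plus cells 1..m
    gcomp <- (hi - lo) / dx
    # drop the padding on the transverse axes
    for (e in seq_len(grid$ndim)) {
      if (e != d) gcomp <- slice_axis(gcomp, e, 1L + seq_len(grid$n[e]))
    }
    out[[d]] <- array(gcomp, dim = face_dims(grid, d))
  }
  out
}

#' Divergence of a staggered vector field
#'
#' The exact discrete adjoint of the staggered pressure gradient, so the
#' pressure projection is exactly idempotent: each cell receives the net face
#' flux divided by the cell size.
#'
#' @param u staggered vector field.
#' @param grid the `fsi_grid`.
#' @return cell-centered scalar array.
#' @export
divergence <- function(u, grid) {
  dx <- grid$dx
  out <- scalar_field(grid)
  for (d in seq_len(grid$ndim)) {
    m <- grid$n[d]
    hi <- slice_axis(u[[d]], d, 2:(m + 1L))
    lo <- slice_axis(u[[d]], d, 1:m)
    out <- out + array((hi - lo) / dx, dim = grid$n)
  }
  out
}

# average staggered component d to cell centers
face_to_center <- function(u, grid, d) {
  m <- grid$n[d]
  0.5 * (array(slice_axis(u[[d]], d, 1:m), dim = grid$n) +
         array(slice_axis(u[[d]], d, 2:(m + 1L)), dim = grid$n))
}

# central difference of a cell-centered array along axis e (one-sided at
# non-periodic boundaries)
cc_derivative <- function(f, grid, e) {
  m <- grid$n[e]
  dx <- grid$dx
  if (grid$periodic[e]) {
    hi <- slice_axis(f, e, c(2:m, 1L))
    lo <- slice_axis(f, e, c(m, 1:(m - 1L)))
    array((hi - lo) / (2 * dx), dim = grid$n)
  } else {
    out <- array(0, dim = grid$n)
    if (m >= 3L) {
      ctr <- (slice_axis(f, e, 3:m) - slice_axis(f, e, 1:(m - 2L))) / (2 * dx)
      out <- assign_axis(out, e, 2:(m - 1L), ctr)
    }
    out <- assign_axis(out, e, 1L,
      (slice_axis(f, e, 2L) - slice_axis(f, e, 1L)) / dx)
    assign_axis(out, e, m,
      (slice_axis(f, e, m) - slice_axis(f, e, m - 1L)) / dx)
  }
}

#' Velocity gradient tensor at cell centers
#'
#' Interpolates the staggered velocity to cell centers and differences it.
#' Returns the full (non-symmetric) tensor `L[i][j] = d u_i / d x_j` as a
#' named list (`xx`, `xy`, ..., row = velocity component, column = direction).
#'
#' @inheritParams divergence
#' @return named list of cell-centered arrays.
#' @export
velocity_gradient <- function(u, grid) {
  nd <- grid$ndim
  ax <- c("x", "y", "z")
  uc <- lapply(seq_len(nd), function(d) face_to_center(u, grid, d))
  out <- list()
  for (i in seq_len(nd)) {
    # along the component's own axis the staggered difference is exact
    out[[paste0(ax[i], ax[i])]] <- {
      m <- grid$n[i]
      array((slice_axis(u[[i]], i, 2:(m + 1L)) - slice_axis(u[[i]], i, 1:m)) / grid$dx,
            dim = grid$n)
    }
    for (j in seq_len(nd)) {
      if (i != j) out[[paste0(ax[i], ax[j])]] <- cc_derivative(uc[[i]], grid, j)
    }
  }
  out
}

#' Rate-of-strain tensor `D = (L + L^T)/2` at cell centers
#'
#' @inheritParams divergence
#' @return symmetric tensor field; in 2D the `zz` component is carried
#'   explicitly (zero for planar velocity fields).
#' @export
strain_rate <- function(u, grid) {
  L <- velocity_gradient(u, grid)
  nd <- grid$ndim
  D <- sym_tensor_field(grid)
  D$xx <- L$xx
  D$yy <- L$yy
  D$xy <- 0.5 * (L$xy + L$yx)
  if (nd == 3L) {
    D$zz <- L$zz
    D$xz <- 0.5 * (L$xz + L$zx)
    D$yz <- 0.5 * (L$yz + L$zy)
  }
  D
}

#' Deviatoric part of a symmetric tensor field
#'
#' Subtracts one third of the full three-component trace (`xx + yy + zz`;
#' `zz` is stored even in 2D) from each diagonal component, so
#' `tr(deviatoric(T)) = 0` to round-off including in plane strain.
#'
#' @param T symmetric tensor field (see [sym_tensor_field()]).
#' @return symmetric tensor field with zero trace.
#' @export
deviatoric <- function(T) {
  tr3 <- (T$xx + T$yy + T$zz) / 3
  T$xx <- T$xx - tr3
  T$yy <- T$yy - tr3
  T$zz <- T$zz - tr3
  T
}

#' Discrete stream function of a 2D staggered velocity field
#'
#' Integrates `d psi / d y = u_x` along y on the grid corners; for a
#' discretely divergence-free field the result is path-independent, and
#' its contour lines are the streamlines (e.g. via
#' [grDevices::contourLines()]).
#'
#' @inheritParams divergence
#' @return matrix of corner values, dim `n + 1`.
#' @export
stream_function <- function(u, grid) {
  stopifnot(grid$ndim == 2L)
  n <- grid$n
  psi <- matrix(0, n[1] + 1L, n[2] + 1L)
  psi[, 2:(n[2] + 1L)] <- grid$dx * t(apply(u$x, 1, cumsum))
  psi
}

#' Q-criterion vortex indicator
#'
#' `Q = (||Omega||^2 - ||S||^2) / 2` from the Frobenius norms of the vorticity
#' tensor `Omega = (L - L^T)/2` and the rate-of-strain tensor
#' `S = (L + L^T)/2`; positive where rotation dominates strain.
#'
#' @inheritParams divergence
#' @return cell-centered scalar array.
#' @export
q_criterion <- function(u, grid) {
  L <- velocity_gradient(u, grid)
  nd <- grid$ndim
  ax <- c("x", "y", "z")[seq_len(nd)]
  S2 <- 0; O2 <- 0
  for (i in seq_len(nd)) for (j in seq_len(nd)) {
    lij <- L[[paste0(ax[i], ax[j])]]
    lji <- L[[paste0(ax[j], ax[i])]]
    S2 <- S2 + (0.5 * (lij + lji))^2
    O2 <- O2 + (0.5 * (lij - lji))^2
  }
  0.5 * (O2 - S2)
}
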