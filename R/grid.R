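#' Create a uniform Cartesian grid
#'
#' Builds the structured, uniform grid all fields in the solver live on.
#' Velocities are stored on faces normal to each axis (staggered/MAC
#' arrangement); scalars and tensors at cell centers. Lengths are
#' dimensionless with the pipe diameter as the unit of length.
#'
#' @param n integer vector of cell counts per axis (length 2 or 3).
#' @param length numeric vector of domain lengths per axis.
#' @param periodic logical vector: is each axis periodic?
#' @param wall_mask optional logical array of dim `n`; `TRUE` marks cells that
#'   belong to the solid wall / exterior (velocity pinned to zero there). The
#'   mask is frozen at construction.
#' @return an object of class `fsi_grid`.
#' @examples
#' g <- grid_create(c(32, 32), c(1, 1))
#' g$dx
#' @export
grid_create <- function(n, length, periodic = rep(FALSE, base::length(n)),
                        wall_mask = NULL) {
  n <- as.integer(n)
  ndim <- base::length(n)
  stopifnot(ndim %in% c(2L, 3L), base::length(length) == ndim,
            base::length(periodic) == ndim, all(n >= 2L), all(length > 0))
  dx <- length / n
  if (diff(range(dx)) > 1e-12 * max(dx)) {
    stop("grid spacing must be uniform across axes (got ",
         paste(signif(dx, 10), collapse = ", "), ")")
  }
  if (is.null(wall_mask)) {
    wall_mask <- array(FALSE, dim = n)
  } else {
    stopifnot(identical(dim(wall_mask), as.integer(n)))
    wall_mask <- array(as.logical(wall_mask), dim = n)
  }
  g <- list(ndim = ndim, n = n, length = as.numeric(length),
            dx = dx[1], periodic = as.logical(periodic),
            wall = wall_mask)
  class(g) <- "fsi_grid"
  g
}

#' @export
print.fsi_grid <- function(x, ...) {
  cat(sprintf("<fsi_grid> %dD, %s cells, dx = %.6g, periodic = %s, %d wall cells\n",
              x$ndim, paste(x$n, collapse = " x "), x$dx,
              paste(ifelse(x$periodic, "T", "F"), collapse = ""),
              sum(x$wall)))
  invisible(x)
}

#' Cell-center coordinates along one axis
#' @param grid an `fsi_grid`.
#' @param axis axis index (1-based).
#' @return numeric vector of cell-center coordinates.
#' @export
grid_centers <- function(grid, axis) {
  (seq_len(grid$n[axis]) - 0.5) * grid$dx
}

#' Face coordinates along one axis (including both ends)
#' @inheritParams grid_centers
#' @return numeric vector of face coordinates, length `n[axis] + 1`.
#' @export
grid_faces <- function(grid, axis) {
  (0:grid$n[axis]) * grid$dx
}

# dims of the staggered component arrays: component d has n[d]+1 faces.
face_dims <- function(grid, d) {
  dm <- grid$n
  dm[d] <- dm[d] + 1L
  dm
}

#' Allocate a cell-centered scalar field
#' @param grid an `fsi_grid`.
#' @param value fill value.
#' @return numeric array of dim `grid$n`.
#' @export
scalar_field <- function(grid, value = 0) array(value, dim = grid$n)

#' Allocate a staggered vector field
#'
#' Component `d` lives on faces normal to axis `d` and has `n[d] + 1` entries
#' along that axis (for periodic axes the first and last planes are images of
#' each other and are kept synchronized by the solver).
#'
#' @inheritParams scalar_field
#' @return list of component arrays (`x`, `y`, and in 3D `z`).
#' @export
vector_field <- function(grid, value = 0) {
  comps <- c("x", "y", "z")[seq_len(grid$ndim)]
  out <- lapply(seq_len(grid$ndim), function(d) array(value, dim = face_dims(grid, d)))
  names(out) <- comps
  out
}

#' Allocate a symmetric tensor field
#'
#' Stores 6 independent components in 3D and 4 in 2D (`xx, xy, yy, zz`): the
#' `zz` component is carried explicitly in 2D so deviatoric parts use the true
#' three-dimensional trace (plane strain).
#'
#' @inheritParams scalar_field
#' @param diag_value value placed on diagonal components (`xx`, `yy`, `zz`);
#'   off-diagonals get `value`.
#' @return named list of cell-centered arrays.
#' @export
sym_tensor_field <- function(grid, value = 0, diag_value = value) {
  comps <- if (grid$ndim == 2L) c("xx", "xy", "yy", "zz") else
    c("xx", "xy", "yy", "xz", "yz", "zz")
  out <- lapply(comps, function(cn) {
    array(if (cn %in% c("xx", "yy", "zz")) diag_value else value, dim = grid$n)
  })
  names(out) <- comps
  out
}

tensor_components <- function(ndim) {
  if (ndim == 2L) c("xx", "xy", "yy", "zz") else c("xx", "xy", "yy", "xz", "yz", "zz")
}

#' Boundary-condition descriptor
#'
#' One entry per boundary patch. Patches are named `xlo`, `xhi`, `ylo`, `yhi`
#' (and `zlo`, `zhi` in 3D); periodic patches must come in matched pairs on the
#' same axis. Per quantity the kind is one of `"periodic"`, `"fixed"`
#' (Dirichlet, with `value`) or `"zerograd"` (homogeneous Neumann).
#'
#' @param ... named patch entries, each a list with fields `kind` and
#'   optionally `value`.
#' @return object of class `fsi_bc`.
#' @examples
#' bc <- boundary_spec(xlo = list(kind = "fixed", value = 5.5),
#'                     xhi = list(kind = "zerograd"))
#' @export
boundary_spec <- function(...) {
  spec <- list(...)
  ok <- c("xlo", "xhi", "ylo", "yhi", "zlo", "zhi")
  if (!all(names(spec) %in% ok)) {
    stop("unknown patch name(s): ", paste(setdiff(names(spec), ok), collapse = ", "))
  }
  for (p in names(spec)) {
    k <- spec[[p]]$kind
    if (is.null(k) || !k %in% c("periodic", "fixed", "zerograd")) {
      stop("patch '", p, "': kind must be periodic, fixed or zerograd")
    }
    if (k == "fixed" && is.null(spec[[p]]$value)) {
      stop("patch '", p, "': fixed-value BC needs a value")
    }
  }
  for (ax in c("x", "y", "z")) {
    lo <- spec[[paste0(ax, "lo")]]; hi <- spec[[paste0(ax, "hi")]]
    lo_per <- !is.null(lo) && lo$kind == "periodic"
    hi_per <- !is.null(hi) && hi$kind == "periodic"
    if (xor(lo_per, hi_per)) stop("periodic patches must pair up on axis ", ax)
  }
  structure(spec, class = "fsi_bc")
}

# default BC from a grid's periodic flags: periodic where flagged, zerograd else
default_bc <- function(grid, value = NULL) {
  axes <- c("x", "y", "z")[seq_len(grid$ndim)]
  spec <- list()
  for (d in seq_len(grid$ndim)) {
    kind <- if (grid$periodic[d]) "periodic" else "zerograd"
    ent <- if (!is.null(value) && !grid$periodic[d]) list(kind = "fixed", value = value) else list(kind = kind)
    spec[[paste0(axes[d], "lo")]] <- ent
    spec[[paste0(axes[d], "hi")]] <- ent
  }
  do.call(boundary_spec, spec)
}
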