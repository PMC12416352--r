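#' Particle shape specification
#'
#' Analytic constructors for the embolic particle shapes. All lengths are
#' dimensionless (pipe diameter = 1, i.e. numerically equal to mm for the
#' 1 mm pipe). The orientation vector `n` (the axis of revolution for the
#' torus/disk, the distinct axis for the ellipsoid) lies in the xy-plane at
#' angle `psi0` degrees from the x-axis (rotation about z):
#' `psi0 = 0` is the "vertical" particle (axis along the flow), `psi0 = 90`
#' the "horizontal" one.
#'
#' @param shape one of `"torus"`, `"disk"`, `"sphere"`, `"ellipsoid"`.
#' @param r,R torus minor and major radius (`R > r > 0`).
#' @param h,rd disk (cylinder) height and radius.
#' @param rs sphere radius.
#' @param a,b,c ellipsoid semi-axes; `b` is carried on the particle axis `n`.
#' @param center numeric length-3 centroid position.
#' @param psi0 initial orientation angle in degrees, in `[0, 90]`.
#' @return object of class `particle_spec`.
#' @examples
#' particle_spec("torus", r = 0.1, R = 0.3, psi0 = 45)
#' @export
particle_spec <- function(shape = c("torus", "disk", "sphere", "ellipsoid"),
                          r = NULL, R = NULL, h = NULL, rd = NULL, rs = NULL,
                          a = NULL, b = NULL, c = NULL,
                          center = c(0, 0, 0), psi0 = 0) {
  shape <- match.arg(shape)
  if (!is.numeric(psi0) || psi0 < 0 || psi0 > 90) {
    stop("psi0 must lie in [0, 90] degrees")
  }
  pars <- switch(shape,
    torus = {
      stopifnot(!is.null(r), !is.null(R))
      if (!(R > r && r > 0)) stop("torus requires R > r > 0")
      list(r = r, R = R)
    },
    disk = {
      stopifnot(!is.null(h), !is.null(rd))
      if (h <= 0 || rd <= 0) stop("disk requires positive h and rd")
      list(h = h, rd = rd)
    },
    sphere = {
      stopifnot(!is.null(rs))
      if (rs <= 0) stop("sphere requires positive rs")
      list(rs = rs)
    },
    ellipsoid = {
      stopifnot(!is.null(a), !is.null(b), !is.null(c))
      if (min(a, b, c) <= 0) stop("ellipsoid requires positive semi-axes")
      list(a = a, b = b, c = c)
    })
  structure(list(shape = shape, pars = pars,
                 center = as.numeric(center), psi0 = as.numeric(psi0)),
            class = "particle_spec")
}

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf("<particle_spec> %s (%s), center (%s), psi0 = %g deg\n", x$shape,
              paste(sprintf("%s=%.4g", names(x$pars), unlist(x$pars)), collapse = ", "),
              paste(sprintf("%.3g", x$center), collapse = ", "), x$psi0))
  invisible(x)
}

# orientation vector of a spec
particle_axis <- function(spec) {
  psi <- spec$psi0 * pi / 180
  c(cos(psi), sin(psi), 0)
}

# map global coordinates (matrix npts x 3) to the particle's local frame:
# local z' along the particle axis n, local y' along global z.
to_local <- function(spec, pts) {
  n <- particle_axis(spec)
  e1 <- c(-n[2], n[1], 0)            # z-hat x n
  e2 <- c(0, 0, 1)
  p <- sweep(pts, 2, spec$center)
  cbind(p %*% e1, p %*% e2, p %*% n)
}

# implicit function: negative inside the particle (local coordinates; the
# ellipsoid's distinct axis b is carried on the particle axis n = local z')
particle_implicit <- function(spec, loc) {
  x <- loc[, 1]; y <- loc[, 2]; z <- loc[, 3]
  switch(spec$shape,
    torus = {
      q <- sqrt(x^2 + y^2) - spec$pars$R
      sqrt(q^2 + z^2) - spec$pars$r
    },
    disk = {
      rad <- sqrt(x^2 + y^2) - spec$pars$rd
      ax <- abs(z) - spec$pars$h / 2
      pmax(rad, ax)
    },
    sphere = sqrt(x^2 + y^2 + z^2) - spec$pars$rs,
    ellipsoid = (x / spec$pars$a)^2 + (y / spec$pars$c)^2 +
      (z / spec$pars$b)^2 - 1)
}

# particle bounding radius (for rasterization windowing)
particle_radius <- function(spec) {
  switch(spec$shape,
    torus = spec$pars$R + spec$pars$r,
    disk = sqrt(spec$pars$rd^2 + (spec$pars$h / 2)^2),
    sphere = spec$pars$rs,
    ellipsoid = max(spec$pars$a, spec$pars$b, spec$pars$c))
}

#' Rasterize a particle to a cell-averaged volume-fraction field
#'
#' Per cell the volume fraction is the fraction of `s^ndim` stratified
#' sub-samples whose implicit value is negative in the particle's local
#' rotated frame (the cell-averaged solid indicator).
#'
#' @param spec a [particle_spec()].
#' @param grid an `fsi_grid` (2D grids place the particle at `z = center[3]`).
#' @param supersampling sub-samples per axis (default 3).
#' @param check_wall error if the particle overlaps the grid's wall mask.
#' @return cell-centered volume-fraction array in `[0, 1]`.
#' @export
rasterize <- function(spec, grid, supersampling = 3L, check_wall = TRUE) {
  s <- as.integer(supersampling)
  stopifnot(s >= 1L)
  dx <- grid$dx
  nd <- grid$ndim
  alpha <- scalar_field(grid)
  # window of cells that can intersect the particle
  rad <- particle_radius(spec) + dx
  rng <- vector("list", nd)
  for (d in seq_len(nd)) {
    cc <- grid_centers(grid, d)
    rng[[d]] <- which(abs(cc - spec$center[d]) <= rad + dx)
    if (length(rng[[d]]) == 0L) return(alpha)
  }
  offs <- ((seq_len(s) - 0.5) / s - 0.5) * dx
  cells <- as.matrix(expand.grid(rng))  # cell index tuples
  centers <- sapply(seq_len(nd), function(d) (cells[, d] - 0.5) * dx)
  sub <- as.matrix(expand.grid(rep(list(offs), nd)))
  frac <- numeric(nrow(cells))
  for (k in seq_len(nrow(sub))) {
    pts3 <- matrix(0, nrow(cells), 3)
    pts3[, seq_len(nd)] <- sweep(centers, 2, sub[k, ], `+`)
    if (nd == 2L) pts3[, 3] <- spec$center[3]
    inside <- particle_implicit(spec, to_local(spec, pts3)) < 0
    frac <- frac + inside
  }
  frac <- frac / nrow(sub)
  alpha[cells] <- frac
  if (check_wall && any(grid$wall[cells][frac > 0])) {
    stop("particle intersects the wall mask at t = 0")
  }
  alpha
}

#' Closed-form particle surface area
#'
#' Torus `4 pi^2 r R`; disk (cylinder) `2 pi rd (rd + h)`; sphere
#' `4 pi rs^2`; ellipsoid via the Thomsen approximation
#' `4 pi ((a^p b^p + a^p c^p + b^p c^p)/3)^(1/p)` with `p = 1.6075`.
#'
#' @param spec a [particle_spec()].
#' @param p Thomsen exponent for the ellipsoid.
#' @return surface area (dimensionless).
#' @export
surface_area <- function(spec, p = 1.6075) {
  with(spec$pars, switch(spec$shape,
    torus = 4 * pi^2 * r * R,
    disk = 2 * pi * rd * (rd + h),
    sphere = 4 * pi * rs^2,
    ellipsoid = 4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)))
}

#' Match a target shape's parameters to a reference surface area
#'
#' Reproduces the construction of same-surface-area particles for the
#' stenotic-pipe embolization test: relative to a reference torus
#' (`r = 0.1, R = 0.3` by default) the sphere radius follows in closed form
#' (`rs = sqrt(pi r R)`), the disk under the constraint `rd = 2 h`, and the
#' ellipsoid (`a = c` free, long axis `b` fixed, default 0.4) by a bracketed
#' root solve of the Thomsen area formula.
#'
#' @param reference reference [particle_spec()] whose area is matched.
#' @param target_shape `"sphere"`, `"disk"` or `"ellipsoid"`.
#' @param b_long fixed ellipsoid long semi-... full axis length? The long
#'   *semi*-axis is `b_long` (0.4, matching the printed shape table).
#' @param p Thomsen exponent.
#' @param center,psi0 passed to the new spec.
#' @return a [particle_spec()] with area equal to the reference's to 1e-10.
#' @export
match_area <- function(reference = particle_spec("torus", r = 0.1, R = 0.3),
                       target_shape = c("sphere", "disk", "ellipsoid"),
                       b_long = 0.4, p = 1.6075,
                       center = reference$center, psi0 = reference$psi0) {
  target_shape <- match.arg(target_shape)
  area <- surface_area(reference, p = p)
  out <- switch(target_shape,
    sphere = particle_spec("sphere", rs = sqrt(area / (4 * pi)),
                           center = center, psi0 = psi0),
    disk = {
      # area = 2 pi rd (rd + h) with rd = 2 h  =>  area = 12 pi h^2
      h <- sqrt(area / (12 * pi))
      particle_spec("disk", h = h, rd = 2 * h, center = center, psi0 = psi0)
    },
    ellipsoid = {
      f <- function(a) {
        4 * pi * (((a * b_long)^p + (a * a)^p + (b_long * a)^p) / 3)^(1 / p) - area
      }
      lo <- 1e-6; hi <- 10 * b_long
      if (f(lo) * f(hi) > 0) stop("no ellipsoid semi-axis root in bracket")
      a <- uniroot(f, c(lo, hi), tol = 1e-14)$root
      particle_spec("ellipsoid", a = a, b = b_long, c = a,
                    center = center, psi0 = psi0)
    })
  stopifnot(abs(surface_area(out, p = p) - area) < 1e-10 * area + 1e-10)
  out
}

#' Cylindrical pipe wall mask (stair-step)
#'
#' Marks as wall every cell whose center lies outside the cylinder of given
#' radius about the pipe axis (axis along x). First-order accurate at the
#' wall by construction.
#'
#' @param grid a 3D `fsi_grid`.
#' @param radius pipe radius.
#' @param center_yz y/z coordinates of the pipe axis (defaults to the domain
#'   center).
#' @return logical array of dim `grid$n`.
#' @export
pipe_mask <- function(grid, radius = 0.5,
                      center_yz = grid$length[2:3] / 2) {
  stopifnot(grid$ndim == 3L)
  y <- grid_centers(grid, 2); z <- grid_centers(grid, 3)
  r2 <- outer((y - center_yz[1])^2, (z - center_yz[2])^2, `+`)
  outside <- r2 > radius^2
  aperm(array(outside, dim = c(grid$n[2], grid$n[3], grid$n[1])), c(3, 1, 2))
}

#' Axisymmetric stenosis wall mask
#'
#' Radius profile along x: the inlet radius at both ends, the throat radius at
#' the midpoint, blended by a smooth cosine taper over the central half of the
#' pipe length.
#'
#' @param grid a 3D `fsi_grid` (pipe axis along x).
#' @param length stenotic pipe length (defaults to the grid's x extent).
#' @param inlet_radius,throat_radius end and mid-pipe radii
#'   (`throat_radius <= inlet_radius`).
#' @param center_yz pipe axis position in the cross-section.
#' @return logical wall-mask array.
#' @export
stenosis_mask <- function(grid, length = grid$length[1],
                          inlet_radius = 1, throat_radius = 0.5,
                          center_yz = grid$length[2:3] / 2) {
  stopifnot(grid$ndim == 3L, throat_radius <= inlet_radius)
  prof <- stenosis_profile(grid_centers(grid, 1), length, inlet_radius, throat_radius)
  if (min(prof) * 2 < 8 * grid$dx) {
    warning("fewer than 8 cells across the stenosis throat")
  }
  y <- grid_centers(grid, 2); z <- grid_centers(grid, 3)
  r2 <- outer((y - center_yz[1])^2, (z - center_yz[2])^2, `+`)
  mask <- array(FALSE, dim = grid$n)
  for (i in seq_len(grid$n[1])) mask[i, , ] <- r2 > prof[i]^2
  mask
}

#' Stenosis radius profile
#' @param x axial coordinates.
#' @inheritParams stenosis_mask
#' @return radius at each `x`.
#' @export
stenosis_profile <- function(x, length, inlet_radius = 1, throat_radius = 0.5) {
  xi <- x - length / 2
  r <- rep(inlet_radius, base::length(x))
  mid <- abs(xi) < length / 4
  r[mid] <- inlet_radius - (inlet_radius - throat_radius) *
    (1 + cos(4 * pi * xi[mid] / length)) / 2
  r
}
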