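# Deformation metrics of the transported particle: isosurface extraction,
# gyration-tensor orientation, cross-section ellipse fits, bending angles,
# projected-circle aspect ratios, and small time-series utilities.

#' Extract the alpha isosurface as a triangulated surface
#'
#' Marching tetrahedra on the cell-centered field at the given iso-level.
#'
#' @param alpha cell-centered array (3D).
#' @param grid the `fsi_grid`.
#' @param level iso-level (default 0.5).
#' @return object of class `isosurface` with `vertices` (n x 3) and
#'   `triangles` (m x 3, 1-based).
#' @export
isosurface <- function(alpha, grid, level = 0.5) {
  stopifnot(grid$ndim == 3L)
  out <- cpp_isosurface(as.numeric(alpha), grid$n, grid$dx, level)
  structure(list(vertices = out$vertices, triangles = out$triangles,
                 level = level), class = "isosurface")
}

#' @export
print.isosurface <- function(x, ...) {
  cat(sprintf("<isosurface> level %.3g: %d vertices, %d triangles, Euler characteristic %d\n",
              x$level, nrow(x$vertices), nrow(x$triangles),
              euler_characteristic(x)))
  invisible(x)
}

#' Euler characteristic of a triangulated surface
#'
#' `V - E + F`; 0 for a torus, 2 for sphere-topology shapes. Used as a
#' resolution diagnostic (logged, not fatal).
#'
#' @param iso an [isosurface()].
#' @return integer.
#' @export
euler_characteristic <- function(iso) {
  tr <- iso$triangles
  ed <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(1, 3)])
  ed <- t(apply(ed, 1, sort))
  nE <- nrow(unique(ed))
  nrow(iso$vertices) - nE + nrow(tr)
}

# unwrap coordinates along a periodic axis about a reference position
unwrap_about <- function(x, ref, L) ref + ((x - ref + L / 2) %% L) - L / 2

#' Volume-fraction-weighted centroid
#'
#' `x_c = sum(alpha x V) / sum(alpha V)`; on periodic axes the domain is
#' shifted (via the circular mean) so the particle is contiguous before
#' averaging.
#'
#' @param alpha volume-fraction array.
#' @param grid the `fsi_grid`.
#' @return numeric position (length `ndim`).
#' @export
centroid <- function(alpha, grid) {
  w <- as.numeric(alpha)
  if (sum(w) <= 0) stop("empty solid: centroid undefined")
  idx <- arrayInd(seq_along(w), grid$n)
  out <- numeric(grid$ndim)
  for (d in seq_len(grid$ndim)) {
    x <- (idx[, d] - 0.5) * grid$dx
    if (grid$periodic[d]) {
      L <- grid$length[d]
      th <- 2 * pi * x / L
      thc <- atan2(sum(w * sin(th)), sum(w * cos(th)))
      ref <- thc / (2 * pi) * L
      x <- unwrap_about(x, ref, L)
      out[d] <- (sum(w * x) / sum(w)) %% L
    } else {
      out[d] <- sum(w * x) / sum(w)
    }
  }
  out
}

#' Volume-fraction-weighted centroid velocity
#'
#' @param alpha volume-fraction array.
#' @param u staggered velocity field.
#' @param grid the `fsi_grid`.
#' @return numeric velocity (length `ndim`).
#' @export
centroid_velocity <- function(alpha, u, grid) {
  w <- as.numeric(alpha)
  if (sum(w) <= 0) stop("empty solid: centroid velocity undefined")
  sapply(seq_len(grid$ndim), function(d) {
    uc <- as.numeric(face_to_center(u, grid, d))
    sum(w * uc) / sum(w)
  })
}

#' Orientation vector and angle from the gyration tensor
#'
#' The gyration tensor is the second-moment tensor of the surface vertices
#' about the centroid; the orientation vector `n` is the eigenvector of its
#' smallest eigenvalue (the torus symmetry axis), with the sign fixed to a
#' non-negative x-component. The angle `psi = acos(|n . x-hat|)` is
#' reported in degrees.
#'
#' @param iso an [isosurface()] (at least 100 vertices).
#' @param center optional centroid (defaults to the vertex mean).
#' @param prev optional previous orientation vector, reused when the two
#'   smallest eigenvalues are degenerate.
#' @param degeneracy_tol relative eigenvalue gap below which the spectrum
#'   is flagged ambiguous.
#' @return list with `n`, `psi` (degrees), `degenerate` flag and the
#'   `eigenvalues`.
#' @export
orientation <- function(iso, center = NULL, prev = NULL,
                        degeneracy_tol = 1e-9) {
  V <- iso$vertices
  if (nrow(V) < 100) stop("need at least 100 surface points for orientation")
  if (is.null(center)) center <- colMeans(V)
  X <- sweep(V, 2, center)
  G <- crossprod(X) / nrow(X)
  eg <- eigen(G, symmetric = TRUE)
  ev <- rev(eg$values)                    # ascending
  vecs <- eg$vectors[, rev(seq_len(3))]
  degenerate <- (ev[2] - ev[1]) < degeneracy_tol * max(ev[3], 1e-300)
  if (degenerate && !is.null(prev)) {
    n <- prev / sqrt(sum(prev^2))
  } else {
    n <- vecs[, 1]
  }
  if (n[1] < 0) n <- -n
  psi <- acos(min(1, abs(n[1]))) * 180 / pi
  list(n = n, psi = psi, degenerate = degenerate, eigenvalues = ev)
}

#' Local coordinate frame of a rotating torus
#'
#' `xi` is the orientation vector `n`; `zeta` is the initial z-axis
#' re-orthonormalized against `xi` (the raw z-axis is generally not
#' orthogonal to a rotating `n`); `eta = xi x zeta` completes a
#' right-handed orthonormal triple `(zeta, eta, xi)`.
#'
#' @param n orientation vector.
#' @param initial_z the z-axis at the initial time (default `c(0,0,1)`).
#' @return list with unit vectors `zeta`, `eta`, `xi`.
#' @export
local_frame <- function(n, initial_z = c(0, 0, 1)) {
  xi <- n / sqrt(sum(n^2))
  z <- initial_z / sqrt(sum(initial_z^2))
  if (abs(sum(z * xi)) > 1 - 1e-9) {
    stop("orientation vector parallel to the initial z-axis: frame undefined")
  }
  zeta <- z - sum(z * xi) * xi
  zeta <- zeta / sqrt(sum(zeta^2))
  eta <- c(xi[2] * zeta[3] - xi[3] * zeta[2],
           xi[3] * zeta[1] - xi[1] * zeta[3],
           xi[1] * zeta[2] - xi[2] * zeta[1])
  list(zeta = zeta, eta = eta, xi = xi)
}

#' Fit a rotated ellipse to planar points
#'
#' Least squares on the implicit residual of
#' `((X cos t + Y sin t)/h)^2 + ((-X sin t + Y cos t)/w)^2 = 1`
#' with a center offset; initialized from second moments and refined by
#' Levenberg-Marquardt.
#'
#' @param X,Y planar coordinates of the loop points.
#' @return list with `center`, `h`, `w`, `theta`, `aspect`
#'   (= min/max axis), and the RMS implicit residual. `NULL` when fewer
#'   than 8 points are supplied.
#' @export
fit_ellipse <- function(X, Y) {
  if (length(X) < 8) return(NULL)
  cx <- mean(X); cy <- mean(Y)
  Xc <- X - cx; Yc <- Y - cy
  C <- cov(cbind(Xc, Yc))
  eg <- eigen(C, symmetric = TRUE)
  theta0 <- atan2(eg$vectors[2, 1], eg$vectors[1, 1])
  h0 <- sqrt(2 * max(eg$values[1], 1e-20))
  w0 <- sqrt(2 * max(eg$values[2], 1e-20))
  resid <- function(p) {
    Xr <- X - p[1]; Yr <- Y - p[2]
    ct <- cos(p[5]); st <- sin(p[5])
    (((Xr * ct + Yr * st) / p[3])^2 + ((-Xr * st + Yr * ct) / p[4])^2) - 1
  }
  fit <- minpack.lm::nls.lm(par = c(cx, cy, h0, w0, theta0), fn = resid,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  h <- abs(p[3]); w <- abs(p[4])
  list(center = c(p[1], p[2]), h = h, w = w, theta = p[5],
       aspect = min(h, w) / max(h, w),
       rms = sqrt(mean(resid(p)^2)))
}

# intersect a triangulated surface with the plane through `origin` with unit
# normal `nv`; returns intersection points (rows)
plane_section <- function(iso, origin, nv) {
  V <- iso$vertices
  s <- as.numeric(sweep(V, 2, origin) %*% nv)
  tr <- iso$triangles
  pts <- list()
  edges <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(1, 3)])
  sa <- s[edges[, 1]]; sb <- s[edges[, 2]]
  cross <- which(sa * sb < 0)
  if (length(cross) == 0) return(matrix(0, 0, 3))
  a <- edges[cross, 1]; b <- edges[cross, 2]
  t <- -sa[cross] / (sb[cross] - sa[cross])
  P <- V[a, , drop = FALSE] + t * (V[b, , drop = FALSE] - V[a, , drop = FALSE])
  unique(P)
}

#' Cross-section ellipse fits on the two axial cutting planes
#'
#' The surface is cut by the two planes through the centroid that contain
#' the orientation axis `xi`: the meridian plane (spanned by `xi` and
#' `eta`, normal `zeta`) and the prime-vertical plane (spanned by `xi` and
#' `zeta`, normal `eta`). Each planar curve splits into its two tube
#' cross-section loops by the sign of the in-plane coordinate along `eta`
#' (forward/back) or `zeta` (right/left); each loop is fitted with a
#' rotated ellipse.
#'
#' @param iso an [isosurface()].
#' @param frame a [local_frame()].
#' @param center particle centroid.
#' @return list of ellipse fits `forward`, `back`, `right`, `left`
#'   (entries `NULL` when a loop has fewer than 8 points).
#' @export
cross_section_ellipses <- function(iso, frame, center) {
  fit_pair <- function(nv, split_axis, in_axis) {
    P <- plane_section(iso, center, nv)
    if (nrow(P) == 0) return(list(pos = NULL, neg = NULL))
    rel <- sweep(P, 2, center)
    Xs <- as.numeric(rel %*% split_axis)  # loop-splitting coordinate
    Ys <- as.numeric(rel %*% in_axis)     # along xi
    pos <- Xs > 0
    list(pos = fit_ellipse(Xs[pos], Ys[pos]),
         neg = fit_ellipse(Xs[!pos], Ys[!pos]))
  }
  mer <- fit_pair(frame$zeta, frame$eta, frame$xi)
  pv <- fit_pair(frame$eta, frame$zeta, frame$xi)
  list(forward = mer$pos, back = mer$neg, right = pv$pos, left = pv$neg)
}

#' Bending angles from opposite cross-section centers
#'
#' For each opposite pair (forward/back on the meridian plane, right/left
#' on the prime vertical) the angle between the two centroid-to-center
#' vectors is folded to a deviation from collinearity
#' (`180 deg - acos(...)`, so an unbent torus reads 0), signed positive
#' when the pair midpoint lies on the `+xi` side of the centroid.
#'
#' Ellipse centers are 2D in-plane coordinates `(split, xi)`; they are
#' lifted back to 3D with the plane's axes.
#'
#' @param ellipses output of [cross_section_ellipses()].
#' @param center particle centroid.
#' @param frame a [local_frame()].
#' @return list with `meridian` and `prime_vertical` angles in degrees
#'   (`NA` when a center is missing).
#' @export
bending_angles <- function(ellipses, center, frame) {
  lift <- function(fit, split_axis) {
    if (is.null(fit)) return(NULL)
    center + fit$center[1] * split_axis + fit$center[2] * frame$xi
  }
  pair_angle <- function(c1, c2) {
    if (is.null(c1) || is.null(c2)) return(NA_real_)
    v1 <- c1 - center; v2 <- c2 - center
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    ang <- 180 - acos(pmax(-1, pmin(1, cosang))) * 180 / pi
    mid <- (c1 + c2) / 2 - center
    sgn <- if (sum(mid * frame$xi) >= 0) 1 else -1
    sgn * ang
  }
  list(meridian = pair_angle(lift(ellipses$forward, frame$eta),
                             lift(ellipses$back, frame$eta)),
       prime_vertical = pair_angle(lift(ellipses$right, frame$zeta),
                                   lift(ellipses$left, frame$zeta)))
}

#' Aspect ratios of the parallel-projected torus outlines
#'
#' Vertices are projected onto the plane perpendicular to `xi` (spanned by
#' `zeta` and `eta`), binned by polar angle about the projected centroid;
#' per-bin minimum and maximum radii trace the inner and outer outlines,
#' each fitted with a rotated ellipse.
#'
#' @param iso an [isosurface()].
#' @param frame a [local_frame()].
#' @param center particle centroid.
#' @param nbins angular bins (default 72).
#' @param min_hole_radius inner outline is reported as missing when the
#'   smallest outline radius falls below this (no resolved hole).
#' @return list with `inner` and `outer` aspect ratios (`NA` if missing)
#'   and the two ellipse fits.
#' @export
projected_circle_ratios <- function(iso, frame, center, nbins = 72,
                                    min_hole_radius = 0.02) {
  rel <- sweep(iso$vertices, 2, center)
  a <- as.numeric(rel %*% frame$zeta)
  b <- as.numeric(rel %*% frame$eta)
  th <- atan2(b, a)
  r <- sqrt(a^2 + b^2)
  bin <- pmin(nbins, 1L + floor((th + pi) / (2 * pi) * nbins))
  rmin <- tapply(r, factor(bin, levels = 1:nbins), min)
  rmax <- tapply(r, factor(bin, levels = 1:nbins), max)
  thc <- -pi + (seq_len(nbins) - 0.5) * 2 * pi / nbins
  fit_outline <- function(rad) {
    ok <- !is.na(rad)
    if (sum(ok) < 8) return(NULL)
    fit_ellipse((rad * cos(thc))[ok], (rad * sin(thc))[ok])
  }
  outer_fit <- fit_outline(rmax)
  inner_fit <- NULL
  if (!anyNA(rmin) && min(rmin) > min_hole_radius) inner_fit <- fit_outline(rmin)
  list(inner = if (is.null(inner_fit)) NA_real_ else inner_fit$aspect,
       outer = if (is.null(outer_fit)) NA_real_ else outer_fit$aspect,
       inner_fit = inner_fit, outer_fit = outer_fit)
}

#' Centered moving average with edge truncation
#'
#' Averages up to `window` points centered on each sample; the window is
#' truncated at the series edges.
#'
#' @param series numeric vector.
#' @param window odd window length.
#' @return smoothed vector of the same length.
#' @export
moving_average <- function(series, window) {
  if (window < 1) stop("window must be at least 1")
  n <- length(series)
  half <- window %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(series[lo:hi])
  }, numeric(1))
}

#' Amplitude spectrum of a uniformly sampled series
#'
#' Magnitude of the discrete Fourier transform of the de-meaned series.
#'
#' @param series numeric vector.
#' @param dt sampling interval.
#' @return list with `frequency` and `amplitude` (up to the Nyquist bin).
#' @export
spectrum_series <- function(series, dt) {
  n <- length(series)
  amp <- Mod(fft(series - mean(series))) / n * 2
  half <- seq_len(n %/% 2 + 1)
  list(frequency = (half - 1) / (n * dt), amplitude = amp[half])
}

#' All deformation metrics for one snapshot
#'
#' Bundles centroid, centroid velocity, orientation, cross-section aspect
#' ratios, bending angles and projected-circle ratios into one row-like
#' record.
#'
#' @param alpha volume-fraction array (3D).
#' @param u staggered velocity field (or `NULL`).
#' @param grid the `fsi_grid`.
#' @param t snapshot time.
#' @param initial_z initial z-axis for the local frame.
#' @param prev_n previous orientation (degeneracy fallback).
#' @param level iso-level.
#' @return list of metrics; `as.data.frame`-able via [metrics_row()].
#' @export
shape_metrics <- function(alpha, u = NULL, grid, t = NA_real_,
                          initial_z = c(0, 0, 1), prev_n = NULL,
                          level = 0.5) {
  # unwrap alpha along periodic x so the isosurface is contiguous
  xc <- centroid(alpha, grid)
  awork <- alpha
  shift <- 0L
  if (grid$periodic[1]) {
    n1 <- grid$n[1]
    mid <- grid$length[1] / 2
    shift <- as.integer(round((mid - xc[1]) / grid$dx))
    awork <- slice_axis(alpha, 1, 1L + ((seq_len(n1) - 1L - shift) %% n1))
    awork <- array(awork, dim = grid$n)
  }
  iso <- isosurface(awork, grid, level)
  ori <- orientation(iso, prev = prev_n)
  frame <- local_frame(ori$n, initial_z)
  ctr_work <- centroid(awork, grid)
  ell <- cross_section_ellipses(iso, frame, ctr_work)
  bend <- bending_angles(ell, ctr_work, frame)
  proj <- projected_circle_ratios(iso, frame, ctr_work)
  uc <- if (is.null(u)) rep(NA_real_, 3) else centroid_velocity(alpha, u, grid)
  list(t = t, centroid = xc, centroid_velocity = uc,
       psi = ori$psi, n = ori$n, degenerate = ori$degenerate,
       aspect = c(forward = if (is.null(ell$forward)) NA_real_ else ell$forward$aspect,
                  back = if (is.null(ell$back)) NA_real_ else ell$back$aspect,
                  right = if (is.null(ell$right)) NA_real_ else ell$right$aspect,
                  left = if (is.null(ell$left)) NA_real_ else ell$left$aspect),
       bending = c(meridian = bend$meridian,
                   prime_vertical = bend$prime_vertical),
       projected = c(inner = proj$inner, outer = proj$outer),
       euler = euler_characteristic(iso))
}

#' Flatten a [shape_metrics()] record to a one-row data frame
#' @param m output of [shape_metrics()].
#' @return one-row data frame with documented columns.
#' @export
metrics_row <- function(m) {
  data.frame(t = m$t,
             xc = m$centroid[1], yc = m$centroid[2],
             zc = if (length(m$centroid) > 2) m$centroid[3] else NA_real_,
             ucx = m$centroid_velocity[1], ucy = m$centroid_velocity[2],
             ucz = m$centroid_velocity[3],
             psi = m$psi,
             aspect_forward = m$aspect[["forward"]],
             aspect_back = m$aspect[["back"]],
             aspect_right = m$aspect[["right"]],
             aspect_left = m$aspect[["left"]],
             bend_meridian = m$bending[["meridian"]],
             bend_prime_vertical = m$bending[["prime_vertical"]],
             proj_inner = m$projected[["inner"]],
             proj_outer = m$projected[["outer"]],
             euler = m$euler)
}
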