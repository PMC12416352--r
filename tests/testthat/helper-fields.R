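# Shared fixtures: analytic velocity fields and surfaces built in code.

# discretely divergence-free staggered field from a stream function sampled
# at grid corners (2D)
stream_velocity <- function(grid, psi_fun) {
  xf <- grid_faces(grid, 1)
  yf <- grid_faces(grid, 2)
  P <- outer(xf, yf, psi_fun)
  u <- vector_field(grid)
  u$x <- (P[, -1] - P[, -ncol(P)]) / grid$dx
  u$y <- -(P[-1, ] - P[-nrow(P), ]) / grid$dx
  u
}

# the single-vortex shear field (classic interface-stretching benchmark)
vortex_velocity <- function(grid, sign = 1) {
  stream_velocity(grid, function(x, y) sign * sin(pi * x)^2 * sin(pi * y)^2 / pi)
}

# simple shear u = (gamma * y, 0) on the staggered grid
shear_velocity <- function(grid, gamma = 1) {
  u <- vector_field(grid)
  u$x <- matrix(rep(gamma * grid_centers(grid, 2), each = grid$n[1] + 1),
                grid$n[1] + 1)
  u
}

# level-set field of a (possibly deformed) torus with axis along x
torus_field <- function(grid, center = c(0.5, 0.5, 0.5), r = 0.1, R = 0.3,
                        squash_x = 1, scale_eta = 1) {
  x <- grid_centers(grid, 1); y <- grid_centers(grid, 2)
  z <- grid_centers(grid, 3)
  f <- array(0, dim = grid$n)
  for (k in seq_along(z)) {
    yy <- outer(rep(1, grid$n[1]), y - center[2])
    # eta = xi x zeta = x-hat x z-hat = -y-hat: scaling along eta = y scaling
    yy <- yy / scale_eta
    zz <- (z[k] - center[3])
    q <- sqrt(yy^2 + zz^2) - R
    xx <- outer(x - center[1], rep(1, grid$n[2])) / squash_x
    f[, , k] <- sqrt((q / r)^2 + (xx / r)^2) - 1
  }
  f
}

# regularly sampled point cloud on an analytic torus surface with axis n
# (regular sampling keeps the second moments exactly symmetric)
torus_cloud <- function(n_axis, r = 0.1, R = 0.3, n_ring = 60, n_tube = 40) {
  gr <- expand.grid(th = 2 * pi * seq_len(n_ring) / n_ring,
                    ph = 2 * pi * seq_len(n_tube) / n_tube)
  th <- gr$th                   # around the ring
  ph <- gr$ph                   # around the tube
  # local frame: z' along the axis
  nv <- n_axis / sqrt(sum(n_axis^2))
  e1 <- c(-nv[2], nv[1], 0)
  if (sum(e1^2) < 1e-12) e1 <- c(1, 0, 0)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nv[2] * e1[3] - nv[3] * e1[2],
          nv[3] * e1[1] - nv[1] * e1[3],
          nv[1] * e1[2] - nv[2] * e1[1])
  rho <- R + r * cos(ph)
  pl <- cbind(rho * cos(th), rho * sin(th), r * sin(ph))
  pl %*% rbind(e1, e2, nv)
}
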