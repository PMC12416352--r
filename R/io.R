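# Configuration parsing, dimensionless conversion, and standard-format
# writers (VTK image data, STL, CSV series, checkpoints).

known_config_keys <- c("case", "re", "mean_velocity_mm_s", "target_mean",
                       "pipe", "solid", "particle", "numerics", "seed",
                       "output", "stenosis", "t_end")

#' Build a case configuration
#'
#' Collects the dimensionless groups the solver consumes. Dimensional
#' inputs (mm, Pa, Pa s, mm/s) are converted using the pipe diameter `D`
#' as length scale, the fluid density `rho` and the velocity scale
#' `U = 2 ubar` (twice the mean velocity), the only convention under which
#' the dimensionless mean inlet velocity is 0.5 and the dimensionless time
#' unit is `D / (2 ubar)`.
#'
#' @param case scenario name (`cavity`, `poiseuille`, `torus_in_pipe`,
#'   `stenosis`).
#' @param re Reynolds number `rho ubar D / mu_f` (pinned; the dimensional
#'   fluid viscosity is derived from it).
#' @param G_pa solid shear modulus in Pa (dimensional) — converted with
#'   `rho = 1000 kg/m^3`, `ubar = 50 mm/s`, `D = 1 mm`; or pass `G_star`.
#' @param G_star dimensionless shear modulus (overrides `G_pa`).
#' @param viscosity_ratio `mu_s / mu_f` in `[1, 10]`.
#' @param target_mean dimensionless bulk velocity target.
#' @param co Courant limit.
#' @param alpha_min clipping threshold.
#' @param reset clip reset tensor (`unit` or `zero`).
#' @param n grid cells per axis.
#' @param length domain lengths.
#' @param t_end dimensionless end time.
#' @param particle a [particle_spec()] or `NULL`.
#' @param n_outer outer (PIMPLE-like) correctors.
#' @param rdf_iters RDF refinement passes.
#' @param seed RNG seed for the optional symmetry-breaking perturbation.
#' @param perturb_amplitude seeded velocity perturbation amplitude
#'   (fraction of U; 0 disables).
#' @param record_every,snapshot_every output cadences (steps).
#' @return object of class `case_config`.
#' @export
case_config <- function(case = "torus_in_pipe", re = 50, G_pa = 100,
                        G_star = NULL, viscosity_ratio = 1,
                        target_mean = 0.5, co = 0.1, alpha_min = 0.1,
                        reset = c("unit", "zero"), n = c(96, 32, 32),
                        length = c(3, 1, 1), t_end = 20,
                        particle = NULL, n_outer = 2L, rdf_iters = 2L,
                        seed = 1L, perturb_amplitude = 0,
                        record_every = 10L, snapshot_every = 0L) {
  reset <- match.arg(reset)
  if (re <= 0) stop("Reynolds number must be positive")
  if (co > 0.5) stop("Courant limit must not exceed 0.5")
  if (viscosity_ratio < 0) stop("viscosity ratio must be non-negative")
  # velocity scale U = 2 ubar; reference rho = 1000 kg/m^3, ubar = 50 mm/s,
  # D = 1 mm => rho U^2 = 10 Pa
  if (is.null(G_star)) G_star <- G_pa / 10
  if (G_star < 0) stop("shear modulus must be non-negative")
  nu_f <- 1 / (2 * re)
  structure(list(case = case, re = re, G = G_star,
                 nu_f = nu_f, nu_s = nu_f * viscosity_ratio,
                 viscosity_ratio = viscosity_ratio,
                 target_mean = target_mean, co = co,
                 alpha_min = alpha_min, reset = reset,
                 n = as.integer(n), length = length, t_end = t_end,
                 particle = particle, n_outer = as.integer(n_outer),
                 rdf_iters = as.integer(rdf_iters), seed = as.integer(seed),
                 perturb_amplitude = perturb_amplitude,
                 record_every = as.integer(record_every),
                 snapshot_every = as.integer(snapshot_every)),
            class = "case_config")
}

#' @export
print.case_config <- function(x, ...) {
  cat(sprintf("<case_config> %s: Re=%g G*=%g nu_s/nu_f=%g grid %s t_end=%g\n",
              x$case, x$re, x$G, x$viscosity_ratio,
              paste(x$n, collapse = "x"), x$t_end))
  invisible(x)
}

#' Load a case configuration from a YAML file
#'
#' Dimensional entries (`G_pa`, `mean_velocity_mm_s`, pipe sizes in mm)
#' are converted to the dimensionless groups. Unknown top-level keys are
#' rejected. If both a Reynolds number and a dimensional fluid viscosity
#' are given and disagree, loading fails and asks the user to pin `re`
#' (the printed parameter tables are mutually inconsistent on this point).
#'
#' @param path YAML file path.
#' @return a [case_config()].
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), known_config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  re <- y$re
  if (!is.null(y$solid$mu_f_pa_s)) {
    # check Re = rho ubar D / mu_f with rho=1000, D from pipe, ubar given
    ubar <- (y$mean_velocity_mm_s %||% 50) / 1000
    D <- (y$pipe$diameter_mm %||% 1) / 1000
    re_dim <- 1000 * ubar * D / y$solid$mu_f_pa_s
    if (is.null(re)) {
      re <- re_dim
    } else if (abs(re_dim - re) > 1e-6 * re) {
      stop("dimensional fluid viscosity implies Re = ", signif(re_dim, 4),
           " but re = ", re, " was requested; the printed parameter tables",
           " disagree here - pin `re` and drop mu_f_pa_s")
    }
  }
  part <- NULL
  if (!is.null(y$particle)) {
    p <- y$particle
    part <- switch(p$shape,
      torus = particle_spec("torus", r = p$r, R = p$R,
                            center = p$center %||% c(0, 0, 0),
                            psi0 = p$psi0 %||% 0),
      disk = particle_spec("disk", h = p$h, rd = p$rd,
                           center = p$center %||% c(0, 0, 0),
                           psi0 = p$psi0 %||% 0),
      sphere = particle_spec("sphere", rs = p$rs,
                             center = p$center %||% c(0, 0, 0),
                             psi0 = p$psi0 %||% 0),
      ellipsoid = particle_spec("ellipsoid", a = p$a, b = p$b, c = p$c,
                                center = p$center %||% c(0, 0, 0),
                                psi0 = p$psi0 %||% 0),
      stop("unknown particle shape: ", p$shape))
  }
  num <- y$numerics %||% list()
  sol <- y$solid %||% list()
  case_config(case = y$case %||% "torus_in_pipe",
              re = re %||% 50,
              G_pa = sol$G_pa %||% 100,
              G_star = sol$G_star,
              viscosity_ratio = sol$viscosity_ratio %||% 1,
              target_mean = y$target_mean %||% 0.5,
              co = num$co %||% 0.1,
              alpha_min = sol$alpha_min %||% 0.1,
              reset = sol$reset %||% "unit",
              n = num$grid %||% c(96, 32, 32),
              length = num$length %||% c(3, 1, 1),
              t_end = y$t_end %||% 20,
              particle = part,
              n_outer = num$n_outer %||% 2L,
              rdf_iters = num$rdf_iters %||% 2L,
              seed = y$seed %||% 1L,
              perturb_amplitude = num$perturb_amplitude %||% 0,
              record_every = num$record_every %||% 10L,
              snapshot_every = num$snapshot_every %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Content hash of a configuration (round-trip identity check)
#' @param config a [case_config()].
#' @return md5 string.
#' @export
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(unclass(config), tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Write fields as VTK image data (.vti, ascii)
#'
#' Cell-centered fields (scalars, vectors interpolated to centers, tensor
#' components) in the XML VTK ImageData format readable by standard VTK
#' viewers.
#'
#' @param fields named list: scalars are arrays of dim `grid$n`; an entry
#'   named `U` may be a staggered vector field (interpolated to centers).
#' @param grid the `fsi_grid`.
#' @param path output file (`.vti`).
#' @return `path`, invisibly.
#' @export
write_vti <- function(fields, grid, path) {
  n3 <- c(grid$n, rep(1L, 3 - grid$ndim))
  con <- file(path, "w")
  on.exit(close(con))
  ext <- sprintf("0 %d 0 %d 0 %d", n3[1], n3[2], n3[3])
  writeLines(c('<?xml version="1.0"?>',
    '<VTKFile type="ImageData" version="0.1" byte_order="LittleEndian">',
    sprintf('<ImageData WholeExtent="%s" Origin="0 0 0" Spacing="%.10g %.10g %.10g">',
            ext, grid$dx, grid$dx, grid$dx),
    sprintf('<Piece Extent="%s">', ext), "<CellData>"), con)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (is.list(f)) { # staggered vector -> cell centers, 3 components
      comps <- lapply(seq_len(grid$ndim), function(d) as.numeric(face_to_center(f, grid, d)))
      while (length(comps) < 3) comps <- c(comps, list(rep(0, prod(grid$n))))
      vals <- as.numeric(rbind(comps[[1]], comps[[2]], comps[[3]]))
      nc <- 3L
    } else {
      vals <- as.numeric(f)
      nc <- 1L
    }
    writeLines(sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
                       nm, nc), con)
    writeLines(paste(format(vals, digits = 9, trim = TRUE), collapse = " "), con)
    writeLines("</DataArray>", con)
  }
  writeLines(c("</CellData>", "</Piece>", "</ImageData>", "</VTKFile>"), con)
  invisible(path)
}

#' Write an isosurface as ascii STL
#' @param iso an [isosurface()].
#' @param path output file.
#' @param name solid name recorded in the file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(iso, path, name = "isosurface") {
  V <- iso$vertices; Tr <- iso$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (t in seq_len(nrow(Tr))) {
    p1 <- V[Tr[t, 1], ]; p2 <- V[Tr[t, 2], ]; p3 <- V[Tr[t, 3], ]
    nv <- c((p2[2]-p1[2])*(p3[3]-p1[3]) - (p2[3]-p1[3])*(p3[2]-p1[2]),
            (p2[3]-p1[3])*(p3[1]-p1[1]) - (p2[1]-p1[1])*(p3[3]-p1[3]),
            (p2[1]-p1[1])*(p3[2]-p1[2]) - (p2[2]-p1[2])*(p3[1]-p1[1]))
    len <- sqrt(sum(nv^2)); if (len > 0) nv <- nv / len
    writeLines(c(sprintf("  facet normal %g %g %g", nv[1], nv[2], nv[3]),
                 "    outer loop",
                 sprintf("      vertex %g %g %g", p1[1], p1[2], p1[3]),
                 sprintf("      vertex %g %g %g", p2[1], p2[2], p2[3]),
                 sprintf("      vertex %g %g %g", p3[1], p3[2], p3[3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Write a metrics time series as CSV
#'
#' One row per snapshot; missing metrics are written as empty cells, not
#' zeros.
#'
#' @param series data frame (e.g. bound [metrics_row()]s or a run's
#'   `series`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  write.csv(series, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Save / load a run checkpoint
#'
#' The checkpoint carries the full field state (including the interface
#' normals used as the reconstruction warm start), the step counter and
#' clock, and the configuration hash, so a reloaded run continues
#' bit-identically.
#'
#' @param result a scenario/run result holding `grid`, `state`, `config`.
#' @param path checkpoint file.
#' @return `path` (write) / the checkpoint list (read).
#' @export
write_checkpoint <- function(result, path) {
  saveRDS(list(grid = result$grid, state = result$state,
               config = result$config,
               config_hash = if (!is.null(result$config)) config_hash(result$config) else NA,
               t = result$state$t, step = result$state$step), path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) readRDS(path)
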