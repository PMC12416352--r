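---
title: "One-field Eulerian fluid-structure interaction for deformable embolic particles: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{eulfsi methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical model

`eulfsi` simulates an incompressible Newtonian fluid coupled to an
incompressible Neo-Hookean visco-hyperelastic solid in a *one-field (full
Eulerian)* formulation: both phases live on one fixed Cartesian grid and
share a single momentum equation. The solid is captured by a volume
fraction $\alpha$ (1 in the solid, 0 in the fluid), transported by

$$\partial_t \alpha + \nabla\cdot(\alpha \mathbf u) = 0,$$

and its strain state by the left Cauchy-Green tensor
$\mathbf B = \mathbf F \mathbf F^T$. To stabilize the divergence form near
the interface the solver transports the corrected tensor
$\tilde{\mathbf B} = \alpha^{1/2} \mathbf B$ (the exponent $1/2$ is fixed
by incompressibility):

$$\partial_t \tilde{\mathbf B} + \nabla\cdot(\mathbf u \tilde{\mathbf B})
  = \mathbf L \tilde{\mathbf B} + \tilde{\mathbf B} \mathbf L^T,
  \qquad \mathbf L = (\nabla \mathbf u)^T.$$

The mixture momentum equation, with equal phase densities $\rho$ and the
volume-fraction-blended viscosity
$\mu = \alpha\mu_s + (1-\alpha)\mu_f$, is

$$\partial_t \mathbf u + \mathbf u\cdot\nabla\mathbf u =
  -\tfrac{1}{\rho}\nabla p_{rgh}
  + \nabla\cdot\!\left[2\big((1-\alpha)\nu_f + \alpha \nu_s\big)\mathbf D\right]
  + \tfrac{G}{\rho}\,\nabla\cdot\!\big(\alpha^{1/2}\,\mathrm{dev}\,\tilde{\mathbf B}\big)
  + \mathbf S,$$

where $G$ is the solid shear modulus, $\mathrm{dev}$ the deviatoric part
with the full three-component trace (carried explicitly as a `zz`
component in planar runs), and $\mathbf S$ the uniform mean-flow forcing
source. Because fluid and solid obey one equation, action/reaction holds
identically everywhere. Gravity is zero by default: the phases have equal
density, so the hydrostatic-subtracted pressure $p_{rgh}$ degenerates to
the dynamic pressure.

Two typesetting ambiguities in the source formulation were resolved on
physical grounds: the elastic term is implemented in the conservative form
$\nabla\cdot(\alpha^{1/2} G\, \mathrm{dev}\tilde{\mathbf B})$, which
follows from substituting $\tilde{\mathbf B}$ into the mixture stress; and
the deviatoric part is taken of $\tilde{\mathbf B}$ (a pure-pressure
isotropic part must not drive flow).

### Nondimensionalization

All quantities are scaled by the pipe diameter $D$, the density $\rho_f$
and the velocity $U = 2\bar u$ (twice the mean velocity). This is the only
convention under which the dimensionless bulk velocity target is $0.5$,
the Courant number is $2\bar u\,\Delta t/\Delta x$, and 200 ms of physical
time maps to $t^* \in [0, 20]$. With $\mathrm{Re} = \rho\bar u D/\mu_f = 50$
the dimensionless kinematic viscosity is $\nu_f^* = 1/(2\,\mathrm{Re}) = 0.01$,
and a shear modulus of $G$ Pa maps to $G^* = G/(\rho U^2) = G/10$.
The printed dimensional fluid viscosity in the source's parameter table is
inconsistent with its stated Reynolds number; the package treats the
Reynolds number as authoritative and `load_config()` refuses configs that
try to impose both.

## Discretization

* **Grid.** Uniform Cartesian cells, staggered (MAC) velocity arrangement:
  scalar and tensor fields at cell centers, each velocity component on the
  faces normal to its axis. This replaces the collocated arrangement with
  Rhie-Chow interpolation used by the reference implementation: on a
  staggered grid checkerboard pressure modes cannot exist, and the
  discrete divergence is the exact adjoint of the pressure gradient, so
  the projection is exactly idempotent. Planar (2D) problems run as a
  one-cell-thick periodic slab, which makes every z-difference cancel
  identically.
* **Interface.** Geometric volume-of-fluid with piecewise linear interface
  construction (PLIC). Normals start from smoothed Youngs gradients
  (warm-started from the previous step), and are refined (2 passes by
  default; the count is configurable because the source does not state
  one) through a reconstruction distance function: signed distances to
  neighboring interface planes, averaged with inverse-square-distance
  weights to each plane's interface center, re-differentiated by a
  weighted least-squares fit over the 27-neighborhood. Plane constants are
  positioned so each truncated cell volume matches $\alpha$ to $10^{-13}$.
  Advection is directionally split with geometric donor-cell fluxes (the
  swept wedge of the donor's plane) and the divergence-consistent
  correction term of Weymouth-Yue type, which keeps the scheme
  conservative to round-off and bounded for $\mathrm{Co}\le 0.5$. The
  split geometric scheme replaces the unsplit face-flux integration of
  isoAdvector with the same contract (sharp, conservative, bounded).
  Cut-cell volumes use piecewise closed forms per plane orientation
  region rather than inclusion-exclusion of nearly equal cubes, which
  would suffer catastrophic cancellation for nearly axis-aligned planes.
* **Tensor transport.** Componentwise third-order WENO upwind fluxes for
  the advection of $\tilde{\mathbf B}$; the stretching source uses
  trapezoidal (Crank-Nicolson) weighting realized as one fixed-point
  corrector pass (Heun), second order in time. Cells below
  $\alpha_{\min} = 0.1$ have $\tilde{\mathbf B}$ reset to the unit tensor
  (pipe cases) or the zero tensor (cavity case); both resets carry zero
  deviatoric stress, so they are force-neutral. The published clipping
  rule also zeroes $\alpha$ itself; applied literally every step this
  erodes solid mass at the leading interface and is incompatible with a
  conservative geometric scheme (and with the sub-0.5% volume-drift
  requirement), so the coupled stepping loop applies only the tensor
  reset by default while `clip_btilde()` exposes the literal rule.
  Evolution is restricted to the band within three cells of the solid:
  outside it the clip resets the tensor anyway, so the restriction is
  exact, not an approximation.
* **Momentum.** Explicit predictor (flux-form second-order upwind with a
  minmod limiter, conservative variable-viscosity stress, elastic force at
  faces from cell-centered $G\alpha^{1/2}\mathrm{dev}\tilde{\mathbf B}$),
  then an incompressibility projection; two outer correctors re-evaluate
  the explicit terms from the corrected velocity (the count is
  configurable; the reference solver's outer-corrector count is unstated).
  Projection backends: a direct eigen-transform along x plus banded
  Cholesky solves over the cross-section for domains whose wall mask is
  x-invariant (cavity, periodic pipe) — divergence after correction is at
  round-off; and matrix-free conjugate gradients for the stenosis,
  preconditioned by the straight-duct transform solver applied as a
  fictitious-domain preconditioner (about 10 iterations per step instead
  of about 100 with Jacobi), iterated until the post-correction divergence
  bound $10^{-8}$ holds.
* **Time step.** $\Delta t = \min(\mathrm{Co}\,\Delta x/|u|_{\max},\;
  \Delta x^2/(12\nu_{\max}),\; 0.5\,\Delta x/\sqrt{G/\rho})$ with
  $\mathrm{Co} = 0.1$. The viscous and elastic safety factors are
  stricter than the bare stability statements ($\Delta x^2/3\nu$ and
  $\Delta x/\sqrt{G/\rho}$) because both terms are integrated explicitly
  here; the viscous factor sits at half the planar forward-Euler limit —
  at three quarters of the limit a slowly growing oscillatory mode
  measurably perturbs long cavity trajectories. A soft-start ramp grows
  $\Delta t$ from $10^{-4}$ by 20% per step.
* **Walls.** The cylindrical pipe is a stair-step mask (cells whose
  centers fall outside the cylinder), first-order accurate at the wall;
  velocities on wall-adjacent faces are pinned to zero, wall cells carry
  $\alpha = 0$ and the reset tensor, and the pressure sees a homogeneous
  Neumann condition there. The pure-fluid Poiseuille verification instead
  uses the axisymmetric reduction, where the wall is exact.

## The axisymmetric pipe reduction

For fully developed single-phase flow the axial momentum equation reduces
to radial diffusion plus the forcing source (the convective term vanishes
identically). `run_poiseuille()` integrates this on vertex-centered radial
nodes with the no-slip value imposed exactly at the wall node. The
discrete radial Laplacian is exact on parabolas, and the bulk velocity is
measured by Simpson quadrature in $r\,\mathrm{d}r$, exact for the cubic
integrand $u\,r$; consequently the steady state of the discrete system
*is* the analytic Hagen-Poiseuille profile, and the reported L2 error
(about $10^{-12}$) measures only the residual of the time integration,
comfortably below the coarsest-mesh reference value of $1.2\times10^{-5}$.
The mean-flow forcing controller adds $(0.5-\bar u)/\Delta t$ as a uniform
source after every step; its accumulator is the pressure-gradient readout,
with the analytic steady value $S^* = 16/\mathrm{Re}_U = 0.16$ recovered
to round-off.

## Scenario presets and what the scaled-down runs show

The published production resolution for the pipe transport problem is a
$320\times64\times64$ box ($L = 5D$, 64 cells per diameter, about 12 cells
across the torus tube). Desk-scale presets in this package use
$72\times24\times24$ ($L = 3D$, 24 cells per diameter) with the torus
minor radius at the top of the published range ($r = 0.125$, $R = 0.3$,
so 6 cells across the tube); horizons are $t^*\le 16$. At this scale the
package reproduces the qualitative transport physics — the inclined torus
rotates monotonically to a plateau near $80^\circ$, the horizontal torus
stays put within a degree, the inclined torus requires less driving
pressure gradient than the horizontal one — but cross-section deformation
amplitudes and fine vibration spectra are under-resolved relative to the
production grid, and quantitative deformation metrics should be read as
scaled-down. The stenosis embolization preset ($48\times16\times16$ over a
$6\times2\times2$ box) resolves the throat with 8 cells but the particles'
fine features with only 2-3, so the robust observables are the torus'
two-peak passage signature (stable across every spacing tried) and its
gentler blockage than the compact sphere and ellipsoid, measured as the
peak hydraulic-resistance excess over a particle-free baseline (with both
end pressures pinned, the raw end-to-end pressure difference is clamped).
The torus-versus-disk margin of that ranking is within resolution noise at
desk scale (it inverts between 48- and 60-cell presets): sub-resolved
particles obstruct roughly by volume, and the published divergence of the
compact shapes — driven by the lubrication-gap pressure spike at wall
contact — does not occur at these grid spacings.

The cavity verification runs exactly the published protocol: unit cavity,
lid velocity 1, solid disk of radius 0.2 at (0.6, 0.5), $\mu_s = \mu_f =
0.01$, $G = 0.05$, $t^* \in [0, 20]$, grids 16-128. Centroid trajectory
errors against the finest grid decrease at close to first order, dominated
by the first-order wall/interface treatment of the elastic stress.

### Stenosis boundary conditions

The source prescribes a fixed alternative pressure of 5.5 at the inlet and
a "fixed gradient of 0" at the outlet. For incompressible flow a Neumann
outlet pressure leaves no imposed driving pressure difference (the 1D
reduction gives $p \equiv 5.5$ and no flow), so the package pins the
outlet pressure to 0 instead: pressure-driven flow with $\Delta p = 5.5$,
velocity zero-gradient at both ends. The reported "pressure drop" series
is measured between the first and last interior cell planes, which is why
it moves when the particle throttles the throat even though the boundary
values are fixed. Divergence of a run (the expected outcome for the
compact shapes at wall contact) is reported as series truncation with a
`diverged` flag, not as an error.

Initial particle placement in the stenosis follows the published sketch:
inclined $45^\circ$, offset 0.5 from the pipe axis (the `y0 = 0.5`
coordinate read in the straight-pipe convention), near the inlet at
$x = 0.7$.

## Other design decisions

* **Initial deformation state.** In the unit-reset (pipe) mode
  $\tilde{\mathbf B} = \mathbf I$ everywhere, the published wall and
  initial value. In the zero-reset (cavity) mode the initial field is
  $\alpha^{1/2}\mathbf I$, the value consistent with the definition
  $\tilde{\mathbf B} = \alpha^{1/2}\mathbf B$ and an undeformed solid; a
  literal all-zero initial tensor would leave the solid permanently
  stress-free. Neither reset produces any elastic force by itself.
* **Incompressibility of the solid** is not re-projected; drift of
  $\det \mathbf B$ is observable through the snapshots and stays small at
  the tested resolutions.
* **Cross-section naming.** The four tube cross-sections are cut by the
  two axial planes through the centroid that contain the orientation axis
  $\xi$: the plane spanned by $(\xi,\eta)$ yields the forward/back loops
  (split by the sign along $\eta$, which has a flow-direction component),
  the plane spanned by $(\xi,\zeta)$ the right/left loops (split along
  $\zeta$). The source's prose places one cutting plane at $(\eta,\zeta)$,
  but that plane contains the torus ring and would cut two concentric
  circles with coincident centers — unusable for the bending-angle
  construction — so the axial-plane reading is adopted. $\zeta$ is
  re-orthonormalized against $\xi$ every frame since the initial z-axis is
  generally not orthogonal to a rotating $n$.
* **Aspect ratios** are reported as min/max axis length in $(0, 1]$, and
  **bending angles** as the deviation from collinearity (0 for an unbent
  torus), positive toward $+\xi$ — conventions consistent with ratio
  curves that start at 1 and decrease and angle curves that grow from 0.
* **Degenerate gyration spectra** (a sphere-like surface) are flagged and
  the previous orientation vector is reused rather than reporting an
  arbitrary eigenvector.
* **Symmetry breaking.** The vertical torus ($\psi_0 = 0$) is an unstable
  equilibrium; a seeded uniform random velocity perturbation of amplitude
  $10^{-4}U$ can be enabled (`perturb_amplitude`) to trigger rotation, and
  is off by default so symmetric cases stay symmetric to round-off.
* **Configs** are YAML (a TOML reader is not among the package's
  dependencies); the schema mirrors the published parameter tables and
  converts dimensional entries.
* **The command line.** `inst/cli/eulfsi` is a thin Rscript over
  `load_config()` and the scenario drivers (`run`, `verify`, `analyze`,
  `convergence` subcommands); all logic lives in the package functions.

## What the tests do and do not show

The test suite validates the discrete contracts (conservation,
boundedness, divergence-freedom, objectivity, closed-form shear solutions,
construct-and-recover shape metrics on analytically deformed tori) and the
published verification quantities at desk scale. Synthetic inputs are
analytic fields and rasterized ideal shapes; they exercise the numerics,
not physiological variability — real vessels are neither straight nor
rigid, blood is not Newtonian at these shear rates, and production-scale
resolution is roughly 2.7x finer per axis than the scaled-down presets
used in the acceptance runs.
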