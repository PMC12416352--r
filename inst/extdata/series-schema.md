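# Column schema of the diagnostics series (CSV)

One row per recorded step of the coupled solver loop.

| column         | meaning                                                        |
|----------------|----------------------------------------------------------------|
| t              | dimensionless time (unit D / 2 ubar)                           |
| dt             | time step used                                                 |
| S              | mean-flow forcing accumulator (pressure-gradient readout;      |
|                | pressure drop = S * L)                                         |
| bulk_velocity  | mean axial velocity over the fluid cells                       |
| solid_volume   | sum of alpha times the cell volume                             |
| max_div        | post-projection max |div u|                                    |
| vof_lost       | volume clamped away by the boundedness redistribution          |
| xc, yc, zc     | alpha-weighted solid centroid (periodic axes unwrapped)        |
| psi            | orientation angle (deg) from the gyration tensor of the        |
|                | alpha = 0.5 isosurface (3D runs; empty when unavailable)       |
| q_in, q_out    | volume flux through the first / last x-face plane              |
| dp             | mean pressure difference between the first and last interior   |
|                | cell planes                                                    |
| poisson_iters  | iterations of the last pressure solve (0 = direct backend)     |
| step           | step counter                                                   |

The per-snapshot deformation metrics table (`metrics.csv`) uses the
columns of `metrics_row()`: t, xc, yc, zc, ucx, ucy, ucz, psi,
aspect_forward/back/right/left, bend_meridian, bend_prime_vertical,
proj_inner, proj_outer, euler. Missing metrics are empty cells.
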