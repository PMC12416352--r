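# Deformable torus in a periodic pipe (scaled-down preset).
# Dimensional entries are converted: G_pa / (rho U^2) with U = 2 ubar.
case: torus_in_pipe
re: 50
target_mean: 0.5
t_end: 12
seed: 1
solid:
  G_pa: 100
  viscosity_ratio: 1
  alpha_min: 0.1
  reset: unit
particle:
  shape: torus
  r: 0.125
  R: 0.3
  psi0: 45
  center: [1.5, 0.5, 0.5]
numerics:
  grid: [72, 24, 24]
  length: [3, 1, 1]
  co: 0.1
  n_outer: 2
  rdf_iters: 2
  record_every: 25
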