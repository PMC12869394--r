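# Closed idealized valve: a single elastic beam spanning a 4 x 1 cm channel,
# pressurized by a ramped inlet traction (CGS units). The steady state is
# hydrostatic with the full 3e5 dyne/cm^2 jump carried across the beam.
title: closed valve
units: CGS
fluid:
  mesh: {generator: cartesian_grid, extents: [[0, 4], [0, 1]], counts: [128, 32]}
  density: 100.0
  viscosity: 10.0
solid:
  mesh: {generator: beam, origin: [1.9894, 0], width: 0.0212, height: 1.0,
         nx: 5, ny: 64}
  material: {model: neo_hookean, E: 5.6e7, nu: 0.4}
  density: 100.0
  clamped: clamped
stabilization: {s_max: 1000}
solver: {dt: 1.0e-3}
bc:
  velocity:
    - {tag: bottom, value: 0}
    - {tag: top, value: 0}
  traction:
    - {tag: left, pressure: {ramp: {p_max: 3.0e5, t_ramp: 0.1}}}
output: {every: 100}
t_end: 3.0
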