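# Oscillating flexible leaflet in pulsatile cross-flow (SI units): large
# periodic deformations of a nearly-incompressible Neo-Hookean strip driven
# by v = 15 y (2 - y) sin(2 pi t) at the inlet.
title: oscillating leaflet
units: SI
fluid:
  mesh: {generator: cartesian_grid, extents: [[0, 4], [0, 1]], counts: [96, 24]}
  density: 100.0
  viscosity: 10.0
solid:
  mesh: {generator: beam, origin: [1.9894, 0], width: 0.0212, height: 0.8,
         nx: 2, ny: 40}
  material: {model: uncoupled_neo_hookean, C0: 1.0e7, kappa_s: 1.0e6}
  density: 100.0
  clamped: clamped
stabilization: {s_max: 1000}
solver: {dt: 1.0e-3}
bc:
  velocity:
    - {tag: bottom, value: 0}
    - {tag: top, value: 0}
    - {tag: left, comp: 1, value: leaflet_profile}
    - {tag: left, comp: 2, value: 0}
output: {every: 100}
t_end: 3.0
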