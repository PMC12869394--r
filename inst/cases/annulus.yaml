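# Immersed annular solid in static equilibrium: a fiber-prestressed annulus
# in a closed box of quiescent fluid; the fiber stress generates a piecewise
# logarithmic equilibrium pressure (SI-like unit system, lengths in m).
title: immersed annulus equilibrium
units: SI
fluid:
  mesh: {generator: cartesian_grid, extents: [[0, 1], [0, 1]], counts: [16, 16]}
  density: 1.0
  viscosity: 1.0
solid:
  mesh: {generator: annulus, R: 0.25, w: 0.0625, n_circ: 224, n_thick: 2,
         center: [0.5, 0.5]}
  material: {model: fiber, mu_s: 1.0}
  density: 1.0
stabilization: {s_max: 1}
solver: {dt: 1.0e-3}
bc:
  velocity:
    - {tag: left, value: 0}
    - {tag: right, value: 0}
    - {tag: bottom, value: 0}
    - {tag: top, value: 0}
output: {every: 5}
t_end: 0.01
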