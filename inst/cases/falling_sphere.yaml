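# Free-falling sphere in a fluid-filled cylinder (CGS units): terminal
# velocity verification against the wall-corrected Stokes solution.
title: falling sphere
units: CGS
fluid:
  mesh: {generator: cylinder_tets, radius: 2.0, height: 4.0, n_across: 8, nz: 20}
  density: 1.0
  viscosity: 10.0
  body_force: [0, 0, -981]
solid:
  mesh: {generator: sphere, a: 0.25, center: [0, 0, 2.5], n_across: 4}
  material: {model: uncoupled_neo_hookean, C0: 33550, kappa_s: 335500}
  density: 1.5
  body_force: [0, 0, -981]
stabilization: {s_max: 1000}
solver: {dt: 5.0e-4}
bc:
  velocity:
    - {tag: side, value: 0}
    - {tag: bottom, value: 0}
output: {every: 20}
t_end: 0.04
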