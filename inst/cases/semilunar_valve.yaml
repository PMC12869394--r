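# Tri-leaflet semilunar valve in an idealized aortic root: configuration
# schema for the full-scale 3D case (CGS units). The vessel and leaflet
# meshes are external Gmsh files (not shipped; the paths below are
# placeholders) -- at full scale the fluid mesh has millions of tetrahedra,
# far beyond this package's desk-scale verification envelope. The schema
# documents how such a case is described; loading it validates the keys,
# and building it fails fast on the missing mesh files.
title: semilunar valve (schema demonstration)
units: CGS
fluid:
  mesh: {msh: meshes/aortic_root_fluid.msh}
  density: 1.1
  viscosity: 0.036
solid:
  mesh: {msh: meshes/semilunar_leaflets.msh}
  material: {model: neo_hookean, E: 2.0e6, nu: 0.4}
  density: 1.0
  clamped: physical_1
stabilization: {s_max: 1000}
solver: {dt: 1.0e-4}
bc:
  velocity:
    - {tag: physical_2, value: 0}          # vessel wall, no-slip
    # inlet plug flow -(Q(t)/A) n is prescribed programmatically; see
    # plug_flow() in the package
output: {every: 100}
t_end: 1.0
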