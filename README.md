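# ifsi — immersed fluid–structure interaction in R

`ifsi` is a desk-scale solver for fluid–structure interaction (FSI) problems
of the kind that arise in cardiovascular biomechanics — thin, soft,
hyperelastic structures such as heart-valve leaflets immersed in pulsatile
incompressible flow. Large leaflet motion makes boundary-fitted (ALE)
methods fragile (mesh distortion, remeshing); `ifsi` instead keeps a fixed
background fluid grid and **immerses** the solid in it:

- **Fluid**: incompressible Navier–Stokes with residual-based variational
  multiscale (VMS) stabilization on equal-order linear elements
  (quadrilaterals/hexahedra/triangles/tetrahedra). The stabilization
  coefficients are built from the element metric tensor
  `G_ij = Σ_k ∂ξ_k/∂x_i ∂ξ_k/∂x_j`:

  ```
  τ_m = [ s·C_T/Δt² + v·Gv + C_I (μ_f/ρ_f)² G:G ]^(-1/2),   τ_c = (τ_m tr G)^(-1)
  ```

  with an interface scaling field `s ≫ 1` in an O(h) band around the
  immersed solid that locally shrinks `τ_m` and boosts `τ_c`, so large
  pressure jumps across thin structures neither pollute the momentum
  stabilization nor leak mass.
- **Solid**: hyperelastic bodies (compressible and nearly-incompressible
  Neo-Hookean, circumferential-fiber prestress) on their own mesh, with the
  fictitious-domain correction: inertia carries the fluid–solid density
  *difference* and the artificial fluid's viscous work is subtracted.
- **Coupling**: a distributed Lagrange multiplier collapsed to the solid
  nodes. One sparse operator `C` (fluid shape functions evaluated at solid
  nodes) interpolates fluid velocity to the solid and spreads — via its
  exact transpose — the solid residual to the fluid equations. The
  multiplier and solid velocities are eliminated, so the monolithic Newton
  system has the size of a fluid-only problem.
- **Time integration**: generalized-α (spectral-radius parameter `ρ∞`),
  second-order in velocity and pressure, with a predictor–multicorrector
  Newton loop and consistent analytic Jacobians (compiled element kernels).

## Worked example: the immersed annulus with an analytic solution

A fiber-prestressed annulus (inner radius 0.25, thickness 0.0625, fiber
modulus μ_s = 1) sits in a closed unit box of quiescent fluid. The hoop
prestress σ = μ_s ê_Θ⊗ê_Θ implies radial equilibrium `dp/dr = −μ_s/r`, so
the exact solution is zero velocity and a piecewise-logarithmic pressure
with jump `μ_s ln(1 + w/R) = ln(1.25) ≈ 0.2231` across the wall.

```r
library(ifsi)
conv <- run_annulus_convergence(N_list = c(16, 32, 64))
round(conv$rates, 3)
#> l2_velocity l2_pressure h1_velocity
#>       1.785       1.448       1.367
conv$table
#>          h  l2_velocity l2_pressure  h1_velocity
#> 1 0.062500 9.498283e-05 0.015322878 0.0022810755
#> 2 0.031250 2.939827e-05 0.005720021 0.0009412597
#> 3 0.015625 8.000626e-06 0.002058197 0.0003430377
```

Each row is one run: an N×N background grid with a companion annulus mesh
(112M×M, M = 2N/16, solid twice as fine), 10 implicit steps of Δt = 1e-3 to
equilibrium, then L2/H1 errors against the analytic solution. The fitted
log–log slopes approach the expected orders (≈2 for velocity in L2, ≈1.5
for pressure in L2 and velocity in H1 — the latter two limited by the
immersed interface, where the pressure kinks across a boundary the grid
does not see).

Other shipped studies: `run_closed_valve()` (a pressurized beam sealing a
channel — the steady state is hydrostatic with the full 3×10⁵ dyne/cm²
(≈225 mmHg) jump carried across the beam), `run_open_valve()` and
`run_oscillating_leaflet()` (large-deformation leaflet motion under
pulsatile inflow), and `run_falling_sphere()` (3D terminal velocity against
the wall-corrected Stokes solution, `stokes_terminal_velocity()`).

Cases can also be described in YAML/JSON (see `inst/cases/`) and run from a
shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/ifsi-run.R", package="ifsi"))') \
    run inst/cases/closed_valve.yaml --output out --max-steps 200
```

which writes per-step Newton diagnostics (CSV), checkpoints, and VTU
snapshots viewable in ParaView.

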