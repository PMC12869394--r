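---
title: "Immersed fluid-structure interaction: methods and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immersed fluid-structure interaction: methods and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the numerical method it
implements: the model equations and their assumptions, the discretization and
coupling choices, the tunable parameters with their defaults and rationale,
what the verification benchmarks do and do not demonstrate, and the known
limitations.

## The problem

Heart-valve dynamics and similar cardiovascular problems couple pulsatile
incompressible flow to thin, soft, hyperelastic structures undergoing large
deformations. Boundary-fitted (ALE) discretizations struggle here: the fluid
mesh distorts as leaflets sweep through the domain and must be rebuilt.
`ifsi` instead keeps a **fixed background fluid grid** and **immerses** the
solid in it (a fictitious-domain method): the fluid equations are extended
into the region occupied by the solid, and the *artificial fluid* there is
constrained to move with the solid. The price is reduced interface
resolution, which the stabilized discretization below is designed to pay
back.

## Fluid: VMS-stabilized incompressible Navier-Stokes

The fluid is Newtonian and incompressible, discretized with equal-order
linear velocity/pressure elements on quadrilaterals, hexahedra, triangles or
tetrahedra. Equal-order pairs are not inf-sup stable, and immersed interfaces
leave the grid under-resolved, so the Galerkin form

$$
\int_\Omega w\cdot\rho_f(\dot v + v\cdot\nabla v - f)\,d\Omega
- \int_\Omega p\,\nabla\cdot w\,d\Omega
+ \int_\Omega 2\mu_f\,\varepsilon(w):\varepsilon(v)\,d\Omega
- \int_{\Gamma_N} w\cdot h\,d\Gamma
+ \int_\Omega q\,\nabla\cdot v\,d\Omega
$$

is augmented with residual-based variational multiscale (VMS) terms with
quasi-static subscales. With the element-interior strong residuals
$r_m = \rho_f(\dot v + v\cdot\nabla v - f) + \nabla p$ (the second-derivative
viscous term vanishes for linear elements) and $r_c = \nabla\cdot v$, the
fine scales are modeled as $v' = -(\tau_m/\rho_f)\,r_m$ and
$p' = -\rho_f\tau_c\,r_c$, and the added terms are the SUPG/PSPG term
$\int (\rho_f v\cdot\nabla w + \nabla q)\cdot(\tau_m/\rho_f) r_m$, the
grad-div term $\int (\nabla\cdot w)\,\rho_f\tau_c r_c$, the convective cross
term $-\int \rho_f\, w\cdot(v'\cdot\nabla v)$ and the Reynolds term
$-\int \rho_f\,\nabla w:(v'\otimes v')$. This is the standard residual-based
closure for this family of stabilized methods; the package treats it as part
of the discretization, not a turbulence model.

The stabilization coefficients are built from the element metric tensor
$G_{ij} = \sum_k \partial\xi_k/\partial x_i\,\partial\xi_k/\partial x_j$
(reference domains: $[-1,1]^d$ for tensor elements, the unit simplex for
simplices — $G$ depends on this convention and the package applies it
consistently):

$$
\tau_m = \left[\, s\,C_T/\Delta t^2 + v\cdot G v
        + C_I (\mu_f/\rho_f)^2\, G\!:\!G \,\right]^{-1/2},
\qquad
\tau_c = (\tau_m\,\mathrm{tr}\,G)^{-1}.
$$

Defaults: $C_I = 36$ (inverse-estimate constant for linear bases), $C_T = 4$.
The **interface scaling** $s \ge 1$ is a nodal field equal to `s_max`
(default 1000) within `band_halfwidth` (default 2) local mesh sizes of any
solid node and 1 elsewhere, interpolated through the pressure basis so the
transition is continuous. Because $s$ multiplies the transient term inside
the bracket, $s \gg 1$ *shrinks* $\tau_m$ — suppressing the SUPG/PSPG terms
where the continuous pressure approximation cannot represent the jump across
a thin immersed structure — and by the reciprocal relation *boosts*
$\tau_c$, penalizing mass loss through the interface. The band is rebuilt
once per time step from the predictor solid position; rebuilding it inside
the corrector loop would let nodes flip discretely between 1 and `s_max`
mid-iteration and spoil convergence.

Boundary conditions: velocity Dirichlet data are imposed strongly by DOF
elimination (time-dependent values evaluated through the generalized-alpha
update so states and rates stay consistent); Neumann boundaries carry a
traction integral (`bc_pressure()` turns an applied pressure $p(t)$ into
$h = -p\,n$); an untagged boundary is traction-free ("do-nothing"). No
backflow stabilization is applied at outlets. For enclosed flows (velocity
Dirichlet everywhere) the pressure is only determined up to a constant; the
case constructor then pins one pressure DOF, and all benchmark comparisons
remove means before measuring errors.

## Solid: immersed hyperelasticity with the artificial-fluid correction

The solid occupies part of the same domain; its weak form on the current
configuration is

$$
\int_{\Omega^s_t} w\cdot(\rho^s-\rho_f)(\ddot u - f)\,d\Omega
+ \int_{\Omega^s_t} \nabla w : \sigma_s \,d\Omega
- \int_{\Omega^s_t} 2\mu_f\,\varepsilon(w):\varepsilon(v_f)\,d\Omega
- \int_{\Gamma^s_N} w\cdot h_s\,d\Gamma ,
$$

with $\rho^s = \rho^s_0/J$ the current density. The density *difference* in
the inertia and the subtraction of the artificial fluid's viscous work remove
the double counting introduced by extending the fluid over the solid; the
assumption behind subtracting only the viscous part is that the solid is
(nearly) incompressible, so the fluid's incompressibility constraint plus the
velocity-matching constraint already control its volumetric behavior, with
the solid's own volumetric terms acting as a penalty on the residual
incompressibility error. $\varepsilon(v_f)$ on the solid is evaluated from
the solid nodal velocities (themselves interpolated fluid values) with solid
shape-function gradients, consistent with the nodal-projection view of the
constraint. The Neumann term is implemented but unused by the benchmarks.

Integrals are evaluated by pulling back to the reference element with the
solid mesh's own quadrature; this is *identical* to quadrature on the current
configuration (the same parametric integrand), so current coordinates never
need to be rebuilt explicitly — displacements carry the motion.

Three constitutive models (all via $\sigma_s = (2/J) F \partial\psi/\partial
C F^T$, closed form):

- **Compressible Neo-Hookean** ($E$, $\nu$):
  $\psi = \tfrac{\mu}{2}(I_1-3) - \mu\ln J + \tfrac{\lambda}{2}(\ln J)^2$,
  the standard textbook form, giving
  $\sigma = (\mu/J)(B - I) + (\lambda \ln J/J) I$.
- **Uncoupled (nearly-incompressible) Neo-Hookean** ($C_0$, $\kappa_s$):
  $\psi = \tfrac{C_0}{2}(\bar I_1 - 3) +
  \tfrac{\kappa_s}{2}(\tfrac12(J^2-1) - \ln J)$ with the volumetric term kept
  verbatim in this form; its stress contribution is
  $\tfrac{\kappa_s}{2}(J - 1/J)I$, which vanishes identically at $J = 1$.
- **Circumferential fiber** ($\mu_s$): $S = \mu_s\,\hat e_\Theta\otimes\hat
  e_\Theta$, a prestress ($\sigma \ne 0$ at $F = I$) representing concentric
  reinforcing fibers; the annulus generator stores $\hat e_\Theta =
  (-\sin\Theta, \cos\Theta)$ analytically per node.

2D problems run as genuinely 2D (plane strain) meshes. The equivalent
one-element-thick 3D arrangement (with all z-components pinned) gives the
same discrete problem at three times the cost.

## Coupling: the nodal constraint matrix

Velocity matching between fluid and artificial fluid/solid is enforced with
a distributed Lagrange multiplier whose basis is collapsed to delta functions
at the solid nodes. Two consequences: (i) the solid velocity is the nodal
interpolation of the fluid velocity at the solid node positions,
$\dot u_A = \sum_B N_B(\phi(X_A,t))\, v_B$; (ii) the multiplier can be
eliminated, and the solid residual lands on the fluid momentum equations
through the transpose of the same sparse operator $C_\lambda$ ("force
spreading"). Interpolation and spreading are exact transposes, columns of
in-mesh nodes sum to one (so spread force is conserved), and the operator's
compact support gives a sharper interface than smeared delta kernels.

Solid nodes that protrude beyond the fluid grid (used deliberately to seal
leaflet edges against vessel walls) are assigned to the nearest element with
extrapolated basis values, capped at 0.5 reference units of parametric
excess; beyond the cap the run aborts rather than extrapolate wildly.

Eliminating the multiplier and the solid velocity leaves a monolithic system
in the fluid unknowns only — the linear system is the *size of a fluid-only
problem*: momentum block $\partial R_{f,m}/\partial \dot V + C_\lambda\,
\partial R_s/\partial \ddot U\, C_\lambda^T$ coupled to the mass block, with
$\Delta\ddot U = C_\lambda^T \Delta\dot V$ recovering the solid update.

## Time integration and the corrector loop

Generalized-alpha for first-order systems, parameterized by the spectral
radius at infinity: $\alpha_m = \tfrac12(3-\rho_\infty)/(1+\rho_\infty)$,
$\alpha_f = 1/(1+\rho_\infty)$, $\gamma = \tfrac12+\alpha_m-\alpha_f$;
default $\rho_\infty = 0.5$ (second-order accurate, moderate high-frequency
damping). The pressure rate is carried as an unknown with the same update as
the velocity rate, which restores second-order accuracy in pressure. The
solid chain is the same family applied twice ($\ddot u \to \dot u \to u$),
giving the documented tangent factors $\partial u_{n+\alpha_f}/\partial
\ddot U_{n+1} = \alpha_f\gamma^2\Delta t^2$, $\alpha_f\gamma\Delta t$ for the
velocity, $\alpha_m$ for the acceleration.

Each step: same-rate predictor ($\dot V_{n+1} = \tfrac{\gamma-1}{\gamma}\dot
V_n$, which keeps $V_{n+1} = V_n$), then Newton corrector passes that (1)
rebuild $C_\lambda$ from the current solid position, (2) slave the solid
rates to the fluid through the constraint, (3) assemble at the intermediate
levels (rates at $t_{n+\alpha_m}$, states at $t_{n+\alpha_f}$), (4) solve the
reduced system, (5) update rates then states. Convergence: residual below
`rtol` (1e-4) times the step's initial residual, or below `atol` (1e-10).

Two numerical policies matter in practice and are configurable:

- **`constraint_rebuilds` (default 2).** The Jacobian does not carry
  $\partial C_\lambda/\partial u$. While position increments are large
  (the first passes) the operator is rebuilt each pass; afterwards it is
  frozen for the rest of the step. Rebuilding indefinitely makes the
  iteration orbit a small limit cycle set by the unmodeled sensitivity
  instead of converging; freezing restores quadratic convergence, and the
  residual floor this leaves is far below the convergence tolerance.
- **`factor_every_pass` (default TRUE) and `refactor_every`.** The sparse
  LU dominates step cost beyond toy sizes. With `factor_every_pass = FALSE`
  the factorization from the first pass of a step is reused for the step's
  later passes, and `refactor_every = k` further re-uses it across k steps
  (appropriate for slowly varying systems such as creeping flow, with a
  forced refactor if a step stops contracting). The convergence check
  always uses the true residual, so accuracy is unaffected — only the pass
  count can grow. The default direct backend is the CSparse LU from the
  Matrix package: its unconditional partial pivoting keeps fill predictable
  on all of this package's stabilized systems, where Eigen's supernodal
  SparseLU (available as an option) can suffer threshold-pivoting fill
  blowup on the coupled matrices.

A GMRES path with an upper-triangular block preconditioner (velocity block
and the pressure stabilization block as a Schur-complement surrogate) is
provided as an option; the direct solver is the default at desk scale.

## Verification benchmarks and what they show

**Immersed annulus in static equilibrium.** A fiber-prestressed annulus
($R = 0.25$, $w = 0.0625$, $\mu_s = 1$) in a closed unit box of quiescent
fluid ($\rho_f = \mu_f = 1$). Radial equilibrium of the hoop prestress gives
the analytic solution: zero velocity and a piecewise-logarithmic pressure
with jump $\mu_s\ln(1+w/R) \approx 0.2231$ across the wall. The convergence
study runs $N\times N$ grids with companion $112M\times M$ annulus meshes
($M = 2N/16$, solid twice as fine), 10 steps of $\Delta t = 10^{-3}$, and
fits least-squares log-log rates of the $L^2$ velocity, mean-removed $L^2$
pressure and $H^1$-seminorm velocity errors over $N = 16, 32, 64$ (the
desk-scale ladder; larger $N$ are available through `N_list`). Expected
rates are approximately 2.0 / 1.5 / 1.5 — interface-limited for pressure and
velocity gradient. This study runs with $s \equiv 1$: it is the equilibrium
verification of the *base* discretization, and the interface scaling
(designed for thin-structure pressure jumps) leaves a small steady
interface current that sits above this benchmark's tiny discretization error
and would mask the velocity rate.

**Closed valve.** A beam (thickness 0.0212 cm, $E = 5.6\times10^7$
dyne/cm², $\nu = 0.4$) spans a $4\times1$ cm channel of heavy fluid
($\rho_f = 100$ g/cm³, $\mu_f = 10$ P), clamped at the bottom wall; the
inlet pressure ramps to $3\times10^5$ dyne/cm² (about 225 mmHg) over 0.1 s.
The continuum steady state is hydrostatic: the beam bows downstream — its
free top end held kinematically by the no-slip wall through the velocity
constraint — and carries the full pressure jump; upstream centerline
pressure $3\times10^5$, downstream 0, with negligible flow when `s_max` is
large (this is the case the interface scaling exists for). The driver runs
$\Delta t = 10^{-3}$ with $\rho_\infty = 0$ and declares steadiness when
the velocity-amplitude envelope stops changing between 50-step windows;
pressures are reported as trailing-window means.

A caveat this package measures and reports rather than hides: at
$\Delta t = 10^{-3}$ the discrete system does not settle into the exact
hydrostatic state but into a small self-sustained flapping limit cycle of
the beam, with a ratchet leak through the immersed interface (residual
speeds of order a tenth of the pre-closure peak). The cycle is a temporal
discretization artifact of the interface treatment — the constraint couples
fluid and solid only at discrete node positions and times — and its
amplitude shrinks roughly like $\Delta t^{1/2}$: restarting the cycle state
with $\Delta t = 10^{-4}$ (the step used in the original study) makes it
decay with a time constant of about 0.12 s. Reaching the fully hydrostatic
state on the 128x32 mesh therefore needs the small step over a second or
more of simulated time, beyond this package's desk-scale envelope; the
pressure plateau, by contrast, is insensitive to the cycle and is the
quantity the verification reports.

**Open valve and oscillating leaflet.** Two qualitative large-deformation
cases: the $8\times1.61$ cm two-leaflet channel at Re 110, and the
$4\times1$ m cross-flow leaflet driven by $v = 15\,y(2-y)\sin(2\pi t)$ with
an uncoupled Neo-Hookean strip ($C_0 = 10^7$ Pa, $\kappa_s = C_0/10$,
$\rho_s = \rho_f$). The published reference data are figures, so acceptance
is *self*-referential: the leaflet tip-displacement series must converge
under mesh refinement, and the cross-flow response must become time-periodic
after the first inflow cycle. The open-valve inflow law is a reconstruction:
the amplitude/time dependence is not printed at the source, so the package
uses a parabolic profile with a half-cosine pulse and an amplitude chosen so
the peak-velocity/channel-height Reynolds number is 110, both configurable.

**Falling sphere.** A nearly rigid sphere ($a = 0.25$ cm, $\rho^s_0 = 1.5$
g/cm³, $C_0 = 33550$ dyne/cm²; $\kappa_s = 10 C_0$ — not printed at the
source, chosen once as stiff enough for near-incompressibility while keeping
the system well-conditioned) falls in a fluid cylinder ($A = 2$ cm, height
4 cm, $\mu_f = 10$ P) under $g = 981$ cm/s². The creeping-flow reference is
$v_t = \tfrac{2g}{9\mu_f}a^2(\rho_s-\rho_f) = 0.68125$ cm/s, wall-corrected
by the axial-cylinder (Bohlin) factor
$K = [1 - 2.10443x + 2.08877x^3 - 0.94813x^5 - 1.372x^6]^{-1}$, $x = a/A <
0.6$, giving $v_t^c = v_t/K \approx 0.505$ cm/s. The published 3% agreement
was obtained on meshes with over $10^7$ DOFs. At desk scale the governing
limitation is resolution across the sphere: the immersed interface widens
the effective hydrodynamic radius by $O(h)$, and with only 2–3 background
cells across the diameter the excess drag is large. Measured plateau speeds
rise toward the corrected value from below as the grid refines — 0.18 cm/s
at $h \approx 0.33$ (12,960 tets, the shipped default), 0.21+ cm/s at
$h = 0.25$ (21,504 tets, still drifting upward when that run was stopped) —
so the qualitative claims hold (monotone approach from rest, plateau well
below the unbounded-domain $v_t$, consistent with wall retardation), while
the plateau still sits below half the corrected speed at the resolutions a
single-CPU desk run can factor (the 3D sparse LU at $\approx 20$k DOFs
costs about 90 s on the reference hardware, and the verification suite runs
dozens of steps). The acceptance test states the bracketing claim as
specified and reports it honestly; the driver's mesh arguments expose the
full-resolution study for machines with more headroom. The sphere's coarse
hexahedral ball also carries about 6% less volume than the exact ball,
proportionally lightening it.

The synthetic geometry generators *are* the study conditions: every
benchmark geometry is constructed from printed dimensions, and no external
data are needed. What passing these tests shows is that the discretization,
coupling and integrator are implemented correctly at verification scale;
what they do not show is physiological fidelity — real valve simulations
add contact, anisotropic tissue models, physiologic waveforms and much finer
meshes, all outside this package's envelope.

## Numerical choices and degenerate inputs

- Point location uses an axis-aligned bounding-box grid over elements and
  Newton inversion of the isoparametric map (30-iteration cap, parametric
  tolerance $10^{-10}$); a point on a shared facet reports the
  lowest-numbered incident element, making runs deterministic. The Newton
  convergence floor is a parametric increment of $10^{-12}$, safely above
  coordinate roundoff amplified by $1/h$.
- Element inversion ($\det F \le 0$), singular isoparametric Jacobians,
  non-finite residuals and failed point searches all raise errors naming the
  element/point; a Newton step that fails to converge raises a condition
  carrying the step report.
- The 6% volume deficit of coarse mapped spheres and the chordal perimeter
  of coarse annuli are properties of the *generated* polyhedral shapes; mesh
  volume tests compare against the polyhedral values exactly and against the
  smooth shapes at the discretization tolerance.
- Checkpointing serializes the full state at a configurable cadence;
  restarting reproduces the uninterrupted trajectory bitwise with the
  direct solver.

## Problem sizes used by the shipped studies

The convergence ladder runs $N = 16, 32, 64$ (largest system about 12.7k
DOFs, about half a minute in total); the closed valve runs the 128x32 /
5x64 mesh pair until the upstream-pressure mean plateaus across 50-step
windows; the leaflet periodicity check runs three inflow cycles on a 48x12
grid and the self-convergence trio runs 48x12 / 72x18 / 96x24 over the
opening transient; the sphere runs 12,960 tetrahedra for 60 steps with a
factorization reused across steps. These sizes were chosen as the smallest
that exhibit the behavior each check measures; where a size materially
limits the result (the sphere's plateau speed) the limitation is stated
above rather than hidden.

## Known limitations

No contact (immersed bodies may interpenetrate where the formulation's
kinematics do not prevent it), no shells, no adaptive refinement, no
non-Newtonian viscosity, no turbulence model beyond the implicit VMS terms,
serial execution only, and the mean-dilatation three-field element is not
implemented (the displacement-only low-order elements here can lock for
strongly incompressible solids; the uncoupled model's moderate $\kappa_s$
values mitigate this at verification scale).
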