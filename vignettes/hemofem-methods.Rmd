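---
title: "Models, numerics and verification in hemofem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, numerics and verification in hemofem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hemofem simulates transient laminar flow and heat transport of a
blood-based gold/silver hybrid nanofluid through a straight vessel segment
carrying a ruptured sidewall dilatation — an aneurysm sac on the upper wall
whose apex has torn open, letting blood leak out. This vignette documents
the models, the discretisation, the parameter choices, and what the
verification suite does and does not demonstrate.

## Effective suspension properties

Blood laden with two nanoparticle species at volume fractions $\phi_1$
(gold) and $\phi_2$ (silver) is treated as a single-phase fluid with
effective constant properties built by applying classical dilute-suspension
mixture laws twice, species 1 first:

* density and volumetric heat capacity: volume-weighted two-step blends,
  e.g. $\rho_{hnf} = (1-\phi_2)\{(1-\phi_1)\rho_f + \phi_1\rho_{s1}\} +
  \phi_2\rho_{s2}$;
* dynamic viscosity: the two-step Brinkman correction
  $\mu_{hnf} = \mu_f\,(1-\phi_1)^{-2.5}(1-\phi_2)^{-2.5}$;
* thermal conductivity: Maxwell's sphere-suspension law applied for gold in
  blood, then for silver in that intermediate fluid.

The species order is fixed (gold = species 1, silver = species 2): the
two-step laws are not symmetric under species exchange, and the order is
asserted by a test. The bundled material table lists blood
($c_p$ 3746 J kg$^{-1}$K$^{-1}$, $k$ 0.52 W m$^{-1}$K$^{-1}$,
$\mu$ 0.003 Pa s, $\rho$ 1063 kg m$^{-3}$), gold and silver. Two caveats
are deliberate:

* the published viscosity column carries a nonstandard unit label; all
  viscosities are interpreted as Pa s, the only reading under which 0.003
  for blood is physical;
* the published silver heat capacity (2354 J kg$^{-1}$K$^{-1}$) is roughly
  ten times the handbook value ($\approx 235$). The printed value is the
  default; `material_table(silver_cp = "handbook")` substitutes 235. The
  choice barely matters for the bundled scenarios: the silver contribution
  enters only through $(\rho C_p)_{hnf}$ at $\phi_2 \sim 10^{-2}$, and the
  simulated temperature field is nearly uniform.

No published run states the volume fractions actually used; the scenario
default is $\phi_1 = \phi_2 = 0.01$, exposed in the configuration, and the
`paper_rupture_no_particles` scenario differs only by $\phi_1=\phi_2=0$, so
nanoparticle effects are isolated by differencing.

## Geometry and meshing

The domain is the 2D cut plane of the vessel: a rectangle of axial length
0.7 m and transverse height 0.09 m (the published vessel dimensions —
anatomically enormous, but adopted as stated). A sidewall sac is modelled
as the major circular segment of a circle of radius 0.025 m whose chord is
a 0.035 m neck opening in the upper wall centred at $z = 0.30$ m; the
rupture orifice is an open gap of 0.008 m arc length at the sac apex. The
sac and orifice dimensions are not published; these defaults were chosen
once to resemble the published geometry sketch and are ordinary
configuration parameters, not data. The sac parameterisation as a circular
arc is likewise an assumption recorded in configuration.

Rectangular domains are meshed with graded structured triangulations. The
sac geometry is meshed by an in-package unstructured mesher: boundary
points placed by a sizing field, interior points from a thinned hexagonal
lattice, DistMesh-style force relaxation, and a vectorised Bowyer-Watson
Delaunay kernel with boundary-edge recovery (missing boundary edges are
split and re-triangulated). The sizing field holds the published minimum
element size (0.0032 m) inside a ball of radius three orifice widths
around the orifice, refines along the arc by the curvature factor, and
grows away from features at the published growth rate 1.13 up to the
published maximum size 0.0169 m. Those sizing values were published for
the study's 3D mesh; they are adopted verbatim as the only printed sizing
data. The mesher is deterministic: the only pseudo-randomness is a seeded
Lehmer generator used to thin the initial lattice, so identical
configurations reproduce identical meshes bit for bit.

Mesh quality is reported as $4\sqrt{3}A/\sum_i \ell_i^2$ (1 for an
equilateral triangle); the metric used by the original solver is not
defined in print, so this standard measure was chosen. The default rupture
mesh has about 1400 triangles with minimum quality $\approx 0.33$.

## Flow solver

Incompressible Navier-Stokes with the full symmetric-gradient viscous
stress $\mu(\nabla v + \nabla v^T)$ and zero body force, discretised with
inf-sup stable Taylor-Hood triangles ($P_2$ velocity, $P_1$ pressure) —
chosen over stabilised equal-order elements to avoid pressure-stabilisation
tuning. Planar mode solves the Cartesian cut-plane equations; axisymmetric
mode solves the $r$-weighted cylindrical reduction (valid when the flow is
independent of the azimuth, hence used only for straight-tube
verification: the sidewall sac breaks axisymmetry). The axisymmetric form
carries the $1/r$ and $u_r/r^2$ hoop terms through the $r$-weighted weak
form and an explicit $2\mu\, u_r v_r / r^2$ contribution.

Boundary conditions:

* **walls**: no-slip, imposed strongly;
* **inlet**: uniform (plug) speed $v_0$ along the axis, imposed strongly at
  every inlet node including the wall corners — the literal reading of the
  stated inflow, kept deliberately unsmoothed; a parabolic profile with the
  same mean is available for verification;
* **outlet**: weak normal traction $-p_0 n$ with $p_0 = 13{,}000$ Pa, the
  stated typical internal artery pressure;
* **rupture orifice**: the published description says only that blood
  leaks; it is modelled as a second traction boundary at
  $\hat p_0 = 12{,}990$ Pa (the lowest published line-graph pressure), so
  orifice outflow is pressure-driven and configurable;
* **open-boundary stabilisation**: the backflow-suppression penalty
  $\beta \rho \max(-v\!\cdot\!n, 0)\,v$ with $\beta = 0.5$, the standard
  form behind the named feature of the original solver, which gives no
  formula.

If a configuration closes every boundary (no traction outlet), the
pressure nullspace is detected and one pressure degree of freedom is
pinned.

Time integration is BDF2 with one implicit-Euler startup step, at
$\Delta t = 0.01$ s to $t_{end} = 2.4$ s. Each step solves the nonlinear
system by Picard iteration with Aitken dynamic relaxation, switching to a
full Newton linearisation once the relative increment falls below
$10^{-3}$; the hybrid matters because the plain Picard map is not
contractive on coarse meshes once the orifice jet develops. Convergence is
declared at relative increment $10^{-8}$ (or an absolute increment below
$10^{-10}$ m s$^{-1}$, the linear-solver noise floor for near-quiescent
states) within at most 60 iterations — more headroom than a typical
default because the impulsive start needs $\sim$30 iterations on coarse
meshes. Linear systems go through a direct sparse LU factorisation, which
desk-scale meshes ($\lesssim 2\times 10^4$ triangles) permit.

The inflow speed is not published. The default $v_0 = 0.08$ m s$^{-1}$ sits
inside the published line-graph velocity range (0.063–0.094 m s$^{-1}$).
The implied Reynolds number $\rho v_0 H/\mu \approx 2.5\times 10^3$ is
logged with a laminar-model advisory. The initial condition is rest
($v = 0$, $p = p_0$): the published $t = 0$ snapshots print values
(2.02 m s$^{-1}$; $2.542\times 10^6$ Pa) irreconcilable with any stated
initialisation and with the later published fields, so they are recorded
as inconsistencies, not modelled.

## Energy equation

One-way coupled advection-diffusion for temperature,
$(\rho C_p)_{hnf}(\partial_t T + v\cdot\nabla T) =
k_{hnf}\nabla^2 T + \mu_{hnf}\Phi$, on $P_1$ elements with SUPG
stabilisation (the blood-scale Peclet number is large). $\Phi$ is the
velocity-gradient invariant
$2(\partial_x u_1)^2 + 2(\partial_z u_3)^2 +
(\partial_z u_1 + \partial_x u_3)^2$, plus $2(u_1/r)^2$ in axisymmetric
mode. All solid borders are insulated (the natural zero-diffusive-flux
condition); the inlet temperature is pinned at 310 K — not stated in
print, but implied by the published 309.99–310 K contour range and body
temperature; open boundaries are advective outflows, the standard
compatible reading of "all borders insulated" for open boundaries. The
properties are temperature-independent, so there is no buoyancy feedback:
the setting is forced convection, and the flow never sees the temperature.

A pressure-work source $\alpha_p T\, Dp/Dt$ can be switched on
experimentally, but is off by default: the fluid is modelled
incompressible, and the published definition of $\alpha_p$
($-p^{-1}\partial_t p$) is not a standard thermal-expansion coefficient.
Whether the original runs included either heat source is unverifiable from
print; viscous dissipation defaults to on, pressure work to off, both
behind flags. At study scales the dissipation heating is
$\mu(6v_0/H)^2 t_{end}/(\rho C_p) \sim 10^{-8}$ K — consistent with the
published near-constant temperature contours, and asserted by a test.

Energy audits use exact boundary quadrature for advective fluxes and the
variationally consistent Dirichlet reactions for conductive inflow, so the
discrete budget closes to round-off on smooth runs; the test uses a
high-conductivity synthetic fluid to keep the front resolved.

## Post-processing and the published comparison surface

`extremes()` scans stored snapshots for per-time maxima/minima of speed,
pressure and temperature. The published per-time "minimum velocity"
(e.g. 0.063 m s$^{-1}$) cannot be a domain minimum — no-slip walls force
zero — so it is read as a line-graph statistic: the package emits both
domain-wide extremes and extremes restricted to the reporting centerline
$x = H/2$, $z \in [0.1L, L]$ (the exact published line is unstated; the
leading 10% is excluded as inlet development), clearly labelled.
`compare_extremes()` ships the published table as reference data and
reports signed relative deviations; because the inflow magnitude, volume
fractions and sac dimensions behind the published numbers are unknown,
flow-rate-dependent cells are reported, never asserted. The
boundary-anchored cells — minimum pressure at the 13,000 Pa outlet level,
maximum temperature at the 310 K band — are asserted in the acceptance
suite at 1% and 0.01 K.

Output times default to the published set $\{0, 0.4, 0.8, 1.2, 2.4\}$ s.
Fields export to legacy-VTK unstructured-grid time series; meshes
round-trip through Gmsh MSH 2.2 with tags as physical groups; tables to
CSV with documented schemas.

## Verification suite and problem sizes

Each builtin verification scenario exercises one closed form:

* `poiseuille_channel`: steady planar channel (0.7 × 0.09 m, $\mu$ 0.003,
  mean speed 0.08) against $u_{max}/U = 1.5$ and
  $\Delta p/L = 12\mu U/H^2$;
* `poiseuille_tube_axisym`: the axisymmetric tube (R = 0.045 m) against
  $u_{max}/U = 2$ and $\Delta p/L = 8\mu U/R^2$ — this exercises the
  $1/r$ terms;
* `mms_convergence`: a manufactured divergence-free trigonometric solution
  with injected body force on unit-square meshes $n = 8, 16, 32$; the
  observed velocity order is $\approx 3.0$ against the formal $L^2$ order 3;
* `conduction_strip`: steady conduction with pinned end temperatures
  against the linear profile;
* `uniform_thermal`: the rupture scenario with dissipation off and uniform
  310 K everywhere; the field must stay uniform to $10^{-9}$ K over 2.4 s,
  which exercises the insulation conditions exactly.

Because the Taylor-Hood continuity equation holds against all $P_1$ test
functions including constants, the integrated discrete divergence — hence
the sum of boundary fluxes — vanishes to solver precision on every step;
the per-step mass-balance defect is logged and asserted below $10^{-6}$
(measured: $\sim 10^{-10}$).

Problem sizes were chosen so the full default rupture transient (about
1400 triangles, 240 steps) completes in roughly ten minutes on one core,
and the verification scenarios in seconds; the conservation acceptance run
uses a far-field-coarsened rupture mesh (`h_max` 0.025 m) with the orifice
refinement kept, since a mesh that under-resolves the orifice jet (one
element across the gap) is not merely inaccurate but drives the nonlinear
iteration into genuine blow-up.

## What the synthetic scenarios do and do not show

The geometry generator emulates the published configuration: a straight
vessel, one upper-wall sac, an apex orifice, graded refinement near the
rupture. It does not emulate patient anatomy (curvature, tapering,
compliance, pulsatile inflow), non-Newtonian rheology, 3D secondary flows,
or any fluid-structure interaction — all outside the model that is being
re-implemented. Passing the verification suite demonstrates that the
discretisation solves the stated equations correctly at the stated sizes;
it does not validate the model against physiological data, and the
published headline fields (3D, ~300k elements, unknown inflow and loading)
are comparison surfaces, not targets. The energy-budget and maximum
principle tests run in parameter regimes chosen to be resolvable
(conductive synthetic fluids); at blood parameters the temperature field
is uniform to within $10^{-2}$ K, so those regimes, not the blood regime,
are where thermal-transport errors would be visible.

## Known limitations

* The plug inlet's corner discontinuity produces a local pressure
  singularity; it is the literal stated condition, and the reported
  quantities (domain pressure minimum, line-graph velocities away from the
  inlet) are insensitive to it.
* The orifice is 2-3 elements wide at the published minimum element size;
  the orifice jet is resolved in the leading-order sense only. Refine
  `h_min` for orifice-local quantities.
* The unstructured mesher has no exact-arithmetic predicates; it is
  intended for the well-spaced point sets its own sizing field produces,
  not as a general-purpose Delaunay library.
* Axisymmetric mode supports no sac, by construction.
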