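---
title: "Desk-scale haemodynamics of extrinsic outflow-graft stenosis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desk-scale haemodynamics of extrinsic outflow-graft stenosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A HeartMate 3 (HM3) left ventricular assist device pumps blood through a
~17 mm polymer outflow graft into the ascending aorta. Biological material
can accumulate in the space between the graft and its bend-relief collar
and compress the graft from outside — extrinsic outflow-graft obstruction
(eOGO). Radiologically, a cross-sectional-area (CSA) reduction above 25%
is graded significant; haemodynamically, what matters is whether the
narrowing produces a meaningful pressure gradient, higher jet velocities,
or turbulent energy losses at device flows of 3.5–5.5 L/min.

`stenoflow` reproduces that assessment chain at desk scale: parametric
stenosed-graft geometries whose narrowest CSAs match the graded
severities, virtual stepwise augmentation of the stenosis, a time-resolved
incompressible flow solver, and the post-processing that turns sampled
fields into the three headline quantities — plane-averaged pressure
gradient (mmHg), peak velocity (m/s), and volume-integrated turbulent
kinetic energy (mJ) — plus Pearson correlation panels over the
severity-by-flow sweep.

## Geometry model

The graft is an axially uniform tube of baseline radius $a$ carrying one
localized extrinsic compression. The inward wall displacement is a
cosine-squared bump over the stenotic extent $L_s$,

$$\delta(s) = \delta_{\max}\cos^2\!\big(\pi\,(s-s_c)/L_s\big),
\qquad |s-s_c| \le L_s/2,$$

zero outside. The bump is continuously differentiable, so the rasterized
wall introduces no artificial pressure spikes; $\delta_{\max}$ is solved
(closed form when concentric, bisection otherwise) so the narrowest
section area equals the requested severity. Virtual augmentation scales
$\delta(s)$ pointwise, which narrows the throat without moving it —
the in-silico analogue of stepwise linear surface deformation.

The deformed cross-section interpolates between a concentric radial
squeeze (eccentricity 0) and a one-sided chord flattening (eccentricity
1, the default: extrinsic material under the bend relief compresses one
wall). Eccentric areas are evaluated by quadrature of the section width;
the closed-form circular-segment expression serves as the independent
cross-check in the tests. Because severity is carried by CSA rather than
section shape, the axisymmetric solver runs on the concentric section of
equal area.

Free parameters the clinical sources do not pin down, fixed once here:

* **Baseline area.** Unstenosed CSA is never reported; it is
  back-computed per case as the mean of `narrowest_CSA / (1 − pct/100)`
  over the three graded severities (≈240 mm² both cases, consistent with
  a 17.5 mm lumen). Both the absolute areas and the integer percent
  reductions round-trip exactly.
* **Stenosis extent and position.** The pressure profile is sampled on
  ten planes 5 mm apart spanning the stenotic segment, implying a
  ~45 mm affected window; the fixtures use a 45 mm extent centred 30 mm
  from the inlet (between the 20 mm and 40 mm radiological measurement
  sites) in a 90 mm domain, leaving an undisturbed outlet run.
* **Curvature.** The real graft curves toward the aorta; the desk solver
  treats the tube as straight (the `curvature_radius` field only bends
  the exported STL surface). Flow lateralization toward the outer
  curvature is therefore not represented — see Limitations.

## Flow solver

Incompressible Navier–Stokes with constant properties
($\rho = 1060\ \mathrm{kg/m^3}$, $\mu = 3.5\times10^{-3}$ Pa·s; shear in
a stenosed graft is high enough that a Newtonian model is adequate),
advanced by a fractional-step (projection) method on a staggered MAC
grid, in axisymmetric $r$–$z$ or planar symmetric half-channel form:

1. explicit predictor: second-order central advection blended with a
   fraction `beta_upwind` (default 0.15) of first-order upwinding —
   deferred-correction-style stabilization for coarse grids — plus
   explicit second-order diffusion with the full axisymmetric metric
   terms;
2. pressure Poisson equation, finite-volume discretized, solved by
   Jacobi-preconditioned conjugate gradients to a relative residual of
   $10^{-6}$, warm-started from the previous step. The solve works on the
   pressure *perturbation* about the outlet reference so the Dirichlet
   boundary is homogeneous and the residual criterion is purely
   divergence-driven;
3. projection of the face velocities, which enforces discrete mass
   conservation cell-by-cell (the flux-mismatch check typically lands
   near $10^{-7}$, far below the $10^{-3}$ requirement).

Boundary conditions mirror the device setting: flat (plug) inlet velocity
matching the device flow (the true pump-outlet profile is unknown; flat
is the conventional choice and the principal inlet-side approximation),
fixed static pressure of 100 mmHg with zero-gradient velocity at the
outlet (aortic reference), rigid no-slip walls, symmetry on the axis. The
HM3 artificial pulse is excluded.

**Wall representation.** Cells are classified fluid by column; the top
fluid velocity node in each column sits a sub-cell gap $h \in [0.5,
1.5]\,\Delta r$ below the analytic lumen radius, and a linear ghost value
$u_g = u\,(1 - \Delta r/h)$ places the no-slip wall at the analytic
radius rather than the nearest cell face. With an aligned wall this
reduces to the classic mirrored ghost, and the clamping keeps the
explicit-diffusion stability bound unchanged. Radial velocities at and
above the wall face are zero (first-order there; radial velocities near
the wall are small).

**Time stepping.** Adaptive: advective CFL 0.4 against the current
velocity maxima, capped by the explicit-diffusion limit
$\Delta t \le \min(\Delta z,\Delta r)^2/(8\nu)$ (the factor 8 accounts
for the doubled radial coefficients at the axis and at mirrored-ghost
walls). A steady-state detector (sup-norm velocity change below
$10^{-6}\,u_{in}$ over 25 steps) freezes converged laminar runs and
replicates the steady field across the remaining sampling window —
fluctuations are then exactly zero, which is what an infinitely long
average of a steady flow would give. Runs default to a washout of three
domain pass-through times followed by a 1 s sampling window at 200
instants; all statistics weight samples uniformly.

**What the desk scale does not capture.** Cluster-scale assessments of
stenotic graft flow use large-eddy simulation on meshes of millions of
cells sampled over several seconds of flow time. At 32 cells per diameter, two dimensions, and a blended advection
scheme, this solver is an under-resolved unsteady laminar/transitional
simulation at the physical Reynolds numbers (≈700–2000). Time-averaged
pressure levels — dominated by convective and viscous losses — are the
quantities that survive this reduction and are the ones the shipped
validation suite bounds; three-dimensional turbulent structures, and hence
absolute TKE magnitudes, are not reproduced (integrated TKE from steady
axisymmetric runs is near zero, far below measured turbulent values).
Patient-specific values (a given patient's worst-cell gradient, the
exact correlation coefficients of a clinical panel) require the
unavailable patient anatomy and are out of scope; only bound-type
claims are checked.

## Haemodynamic metrics

* **Plane pressures.** Ten planes 5 mm apart centred on the narrowest
  station (domain midpoint if no stenosis is identifiable; the set is
  shifted inward if it would leave the domain). Each plane takes the
  area-weighted mean pressure over the lumen cells of the nearest cell
  layer — robust on masked grids — then a uniform time average, reported
  in mmHg.
* **Pressure gradient** = maximum plane mean pressure − 100 mmHg
  reference. Since the outlet holds the reference, this measures the
  non-recovered losses downstream of the maximum-pressure plane.
* **Peak velocity.** Default: maximum over cells of the time-averaged
  velocity magnitude (matching how mean-velocity-magnitude fields are
  displayed and read); the maximum over instants is available via
  `mode = "instant"`. For steady flow both coincide.
* **Reynolds decomposition.** Per cell and component, the fluctuation
  RMS uses the $1/N$ normalization,
  $u' = \sqrt{\tfrac1N \sum_i (u_i - \bar u)^2}$, and
  $TKE = \tfrac12 \rho\,(u'^2 + \upsilon'^2 + w'^2)$ holds exactly by
  construction. The axisymmetric solver has no azimuthal component
  ($w' = 0$); the synthetic field fixtures carry all three so the
  identity and the Monte-Carlo oracle are exercised in full.
* **Integrated TKE** is the lumen-volume integral of the TKE density,
  in millijoules. The integration volume behind reported mJ values is
  not standardized; the whole graft lumen is used here.

## Sweep and statistics

`run_sweep()` runs the 3 severities × 3 flows grid per case (18
simulations over two cases), deterministic given the configuration, with
optional content-hash caching; failed cells are reported, never dropped.
`correlation_panel()` pools the nine cells per case — matching the
per-case statistical design — and reports Pearson $R$ with the exact
small-sample two-sided $p$ (the $t$ transform with $n-2$ degrees of
freedom, via `stats::cor.test`; a brute-force product-moment
implementation is the test oracle). Because "stenotic severity" can be
read as narrowest CSA or as ordinal severity, both encodings are
reported (negative $R$ against CSA means the quantity grows as the lumen
narrows). No multiple-testing correction is applied, matching the
single-panel design. Zero-variance inputs raise an undefined-correlation
error rather than returning $R = 0$.

## Numerical choices and degenerate inputs

* Unit constants are fixed: 1 mmHg = 133.322 Pa, 1 L/min = 1/60000 m³/s;
  pressures are Pa internally, mmHg in all user-facing output.
* Reported percentages round half away from zero (23.53 → 24,
  17.89 → 18), the convention consistent with all reported radiological
  pairs.
* Zero flow is a valid input: the fields stay identically zero at the
  reference pressure, and the flux-mismatch check is guarded against the
  0/0 limit.
* Rasterization requires ≥8 cells per diameter and rejects throats
  narrower than 4 cells; total occlusion anywhere is an error at
  geometry build/augment time.
* The sinusoidal fixture refuses non-integer period counts (they would
  bias the RMS); the Gaussian fixture takes an explicit seed and restores
  the global RNG state.

## Problem sizes used in the shipped analyses

The default study configuration is 32 cells per diameter (90 mm × 8.7 mm
half-plane, ≈165×16 cells), washout of three pass-through times, 1 s
sampling at 200 instants — a deliberate desk-scale choice that keeps a
full 9-cell case sweep in minutes on one CPU while staying inside the
asymptotic range established by the refinement study (16/32/48 cells per
diameter differ by well under 0.1 mmHg in time-averaged pressure level on
the open tube). The oracle checks (Poiseuille at Re 50, the
Bernoulli–Poiseuille bracket at the severest condition) run at 16–32
cells per diameter.

## Repository shape

The package is organised as an analysis workflow: numbered drivers under
`analysis/` (geometry build and verification, radiological grading,
solver validation, the 18-run sweep, correlation panels) are thin
narratives over the exported functions, writing their tables under
`results/`; all computation lives in `R/` (with the solver kernel in
`src/`) where the tests and `scripts/acceptance.R` exercise it. The
config/report layer (`load_config()`, `write_report()`,
`validate_solver()`) plus these scripts constitute the command-line
surface; no separate shell wrapper is provided.

## Known limitations

* Straight axisymmetric (or planar) idealization: no graft curvature, no
  patient-specific lumen irregularity, no bend-relief hardware shape, so
  no U-shaped flow lateralization.
* No turbulence model: TKE magnitudes are lower bounds appropriate only
  for qualitative comparison between conditions.
* Rigid walls, constant inflow (no artificial pulse), flat inlet profile.
* Stair-step column masking in the axial direction (sub-cell accuracy is
  radial only); pressure levels converge, but wall shear is first-order
  near stair transitions and is deliberately not reported.
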