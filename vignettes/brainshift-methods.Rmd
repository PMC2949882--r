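---
title: "Biomechanical brain-shift models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomechanical brain-shift models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After a craniotomy the brain settles, sags and bulges — typically by a few
millimeters near the opening — so the high-resolution pre-operative MRI no
longer matches intra-operative anatomy. `brainshift` estimates that
deformation with patient-adapted biomechanical finite-element models guided
by a handful of landmark correspondences that a surgeon or navigation system
can provide during surgery: the models are solved on a tetrahedral mesh of
the brain, and their material and load parameters are fitted so the
predicted landmark displacements match the observed ones.

Two models are provided.

**Linear "mechanical" model.** Small-strain isotropic elasticity,
`K u = F`, assembled on 4-node (constant-strain) tetrahedra. Defaults
`E = 3000` Pa, `nu = 0.45` are the values commonly used for brain
parenchyma.

**Nonlinear hyperelastic model.** A single-phase continuum under large
deformation with a polynomial strain-energy density in the invariants of
the left Cauchy–Green tensor `B = F F'`:

$$ W = (1-g)\sum_{1 \le i+j \le 2} C_{ij0}\,(J_1-3)^i (J_2-3)^j
     \;+\; \tfrac{\kappa}{2}\,(\sqrt{J_3}-1)^2, $$

with $J_1 = \operatorname{tr}B$,
$J_2 = (J_1^2 - \operatorname{tr}B^2)/(2J_3)$, $J_3 = \det B$. The model
is the stationary (long-time) limit of a hyper-viscoelastic law: of the
instantaneous stiffness only the fraction $1-g$ survives relaxation, where
$g = g_1 + g_2$ sums the relaxation coefficients; the characteristic times
only shape the transient and do not enter the stationary solve, so they are
stored for provenance only. Defaults are the literature brain values
`C100 = C010 = 263` Pa, `C110 = 0`, `C200 = C020 = 491` Pa, `g1 = 0.450`,
`g2 = 0.365`.

Two deliberate choices in this energy deserve a note:

- *The `J2` convention.* The `J2` used here carries a `1/J3` scaling — it
  is not the classical second principal invariant, and it differs from the
  isochoric invariants of the usual compressible Mooney–Rivlin splits. We
  implement it exactly as written. One visible consequence is that the
  second-invariant terms contribute to the volumetric response: the
  linearized first Lamé parameter is about 3% larger than $\kappa$ at the
  default coefficients, which is why `small_strain_moduli()` extracts the
  equivalent `(mu, lambda)` from the analytic tangent at identity instead
  of assuming `lambda = kappa`. The shear modulus equals
  $2(1-g)(C_{100}+C_{010})$ exactly (194.62 Pa at the defaults). Another
  consequence: with $C_{100} \ne C_{010}$ the undeformed state carries a
  (small) hydrostatic residual stress; at the defaults the two are equal
  and the reference state is stress-free.
- *The volumetric penalty.* The published polynomial is silent on
  volumetric response, so a standard penalty
  $\kappa/2(\sqrt{J_3}-1)^2$ closes the model. The default
  `kappa_vol = 50` kPa makes the material nearly incompressible
  (equivalent `nu` about 0.498). Note the tension with the linear model's
  `nu = 0.45`: matching that value exactly would need
  $\kappa \approx 1.9$ kPa given the soft long-time shear modulus. We keep
  the near-incompressible default — brain tissue is water-dominated — and
  expose `kappa_vol` as a parameter.

## Discretization and solvers

Both models use 4-node tetrahedra with linear shape functions. Because the
displacement gradient is constant on such an element, a single quadrature
point is *exact* for the stiffness, the residual and the tangent; we
therefore use a one-point rule throughout (a higher-order rule would
reproduce the same numbers at a multiple of the cost).

The nonlinear model is formulated total-Lagrangian on the reference mesh:
the stationary virtual-work equations are equivalent at equilibrium to the
current-configuration statement, and the fixed reference frame makes the
Newton linearization and the implementation far more robust. The first
Piola–Kirchhoff stress `P = dW/dF` and the 9×9 tangent `dP/dF` are
analytic (derived through `S = dW/dB` and the chain rule; the Cauchy
stress is the push-forward `P F'/J`). Both were validated against central
finite differences before being frozen into the compiled kernels, and the
test suite re-checks them.

- **Linear solve.** Sparse symmetric assembly with the material split
  `K = lambda K_lam + mu K_mu` precomputed per mesh, so re-assembly inside
  the optimizer costs one sparse axpy; Cholesky factorization of the
  reduced free-dof system (conjugate gradients behind `solver = "cg"`,
  tolerance 1e-10). Residual checked against 1e-8.
- **Nonlinear solve.** Load stepping (5 equal increments by default, 3
  inside the optimizer) with a full Newton iteration per step: analytic
  tangent, sparse Cholesky (LU fallback if a trial tangent is indefinite),
  residual-decrease line search with up to 6 step halvings, relative
  residual tolerance 1e-8 (absolute floor near machine precision for
  zero-load cases). An inverted trial element makes the energy infinite
  and simply triggers a halving. A warm-start entry (`u0`) applies the
  full load in one step from a nearby solution and falls back to
  incremental loading — the optimizer uses it to cut repeated solves
  roughly threefold.

**Boundary conditions.** The craniotomy scheme labels every boundary
triangle `FIXED` (zero displacement — the skull-constrained surface),
`EXPOSED_RIM` (traction-free) or `EXPOSED_CENTER` (force-loaded). The
total cap force is distributed over the exposed-center nodes with
triangle-area weights and sums to the prescribed vector exactly; on very
coarse meshes a cap corner node can simultaneously touch a `FIXED`
triangle, in which case it is constrained, carries no load, and the
weights renormalize over the free cap nodes. Dirichlet constraints are
imposed in the classical rigidity-matrix convention (zeroed rows and
columns, unit diagonal, zero right-hand side), which preserves symmetry;
the solvers internally eliminate the constrained equations, which is
algebraically identical and tested as such.

## The sphere phantom

The synthetic study runs on a 22 cm sphere with a polar craniotomy:
boundary triangles within `theta_center` (default 10°) of the cap axis
form the loaded center, within `theta_rim` (default 25°) the traction-free
rim. The published study does not quantify the angular cap size; these
defaults are configuration-exposed placeholders sized to resemble a
typical exposure.

The mesh is generated deterministically by mapping a structured cube grid
onto the ball (six-tetrahedra Kuhn cells, radial max-norm-to-Euclidean
map), with element count `6 n^3` controlled by `target_edge`
(`n = round(diameter/target_edge)`): `n = 7` gives 2058 tetrahedra
(the linear-model study size), `n = 5` gives 750 (nonlinear),
`n = 11` gives 7986, comparable to the published 9028-element sphere. The
faceted mesh is inscribed in the sphere, so a final uniform scaling
matches its volume to the analytic ball volume (node radii grow by well
under one element edge; angles are unchanged). Tetrahedra below
`1e-12` m^3 are rejected, and a cap too small for the resolution raises an
error naming the smallest representable half-angle.

## Units, and the magnitude of the published forces

Everything internal is SI (m, Pa, N); error reports convert to mm to match
the published tables. The study's printed force values (1500 and
−300/300/300) come without units. Read as newtons of total cap force they
would produce multi-meter displacements at kilopascal moduli — and the
published sub-millimeter landmark errors imply millimeter-scale
displacements. A mm–Pa unit system, whose force unit is the millinewton,
reconciles the numbers: we therefore read the printed values as mN, i.e.
defaults of `(1.5, 1.5, 1.5)` N (linear) and `(-0.3, 0.3, 0.3)` N
(nonlinear) total cap force. With these, the linear sphere solution peaks
at ≈ 8.9 mm on the exposed cap — a realistic brain shift.

## Landmarks, cost, and optimization

Landmark pairs carry a pre-operative position, an observed intra-operative
position, and a `TRAIN`/`TEST` role. Predicted positions are barycentric
interpolations of the nodal displacement at the (cached) containing
tetrahedron. The optimization cost is the **sum** of Euclidean distances
between predicted and observed positions of the TRAIN landmarks — reports
quote the **mean** (and per-axis mean/max absolute errors), keeping the
fitted quantity and the reported quantity distinct.

`optimize_parameters()` minimizes the cost with Nelder–Mead (`stats::optim`)
over the free parameters — `E, nu, Fx, Fy, Fz` (linear) or
`C100, C010, C200, C020, g, Fx, Fy, Fz` (nonlinear; `C110` stays at its
tabulated zero, the characteristic times never enter the stationary
problem, `kappa_vol` is held fixed). Since Nelder–Mead is unconstrained,
parameters are searched in a rescaled unconstrained space: log-scale for
moduli, logistic maps for `nu` (onto (0, 0.5)) and `g` (onto (0, 1)),
force components scaled by the initial force magnitude. Every trial point
is therefore feasible by construction; a forward-solver failure inside the
search is answered with a large penalty cost and counted, never fatal
(a failure at the initial point is an immediate error). Stopping uses a
relative cost tolerance of 1e-6 and at most 500 iterations per round;
optional restarts re-inflate the simplex around the incumbent. The best
parameters ever evaluated are returned, so the final cost never exceeds
the initial one.

## The synthetic recovery experiment

`run_recovery()` reproduces the sphere study as an *inverse crime*, openly:
the ground-truth displacement is produced by the same forward solver that
the optimizer later inverts, because no independent truth exists for the
synthetic phantom (the published simulation has the same structure). The
protocol per seed: forward-solve at the true parameters; sample 20 landmark
pre-positions uniformly in a shell under the exposed surface (polar angle
up to `theta_rim + 10°`, depth 5–15 mm below the surface — the lower bound
keeps samples inside the faceted coarse meshes, mirroring how landmarks
concentrate near the exposure where displacements are largest); displace
them through the true field (optionally adding Gaussian noise, default
`sigma = 0`); split 10/10 into TRAIN/TEST; multiply each free true
parameter by `1 + U(-0.2, 0.2)` to form the initial guess (`nu` clamped
below 0.5); optimize on TRAIN; report per-axis and Euclidean errors on
both splits plus a true/initial/recovered parameter table. Identical
configurations reproduce identical results; `compare_models()` runs both
models on one phantom and identical landmark geometry.

Problem sizes were chosen to keep a full recovery at the scale of tens of
seconds (linear, 2058 tets) to a couple of minutes (nonlinear, 750 tets,
3 load steps within the optimizer): small enough to iterate with, large
enough to resolve the craniotomy cap.

## What recovery can and cannot identify

Two exact *gauge freedoms* of the landmark cost matter when reading
recovered parameters:

- **Linear model:** the displacement field depends on the load and
  stiffness only through `F/E` (and `nu`). Scaling `E` and all force
  components together changes nothing a landmark can see. Noiseless
  recovery therefore pins `nu` (we observe deviations around 1e-6) and the
  ratio `F/E` essentially to machine precision, while the *absolute* `E`
  carries the gauge: across seeded restarts from 20%-perturbed starts the
  recovered `E` scatters by hundreds of Pa even as train/test errors sit
  at 1e-6 mm. The simplex drifts freely along the zero-cost ray, and its
  landing point is an artifact of the search path, not a measurement.
- **Nonlinear model:** scaling all `C_ij0` by `alpha` while sending
  `(1-g) \to (1-g)/alpha` leaves the energy identical, so only the
  products `(1-g) C_ij0` are identifiable; the volumetric penalty (held
  fixed) breaks the force-vs-stiffness scaling only weakly. In addition,
  at the small strains the default study produces, `(J_1-3)` and
  `(J_2-3)` are second order in strain, so the quadratic coefficients
  `C200`, `C020` are excited at fourth order — their individual values are
  practically invisible to the data even before the gauge argument.

Consequently the package's recovery experiment reproduces the published
*error* levels easily but cannot reproduce the published tight deviation
bands for `E` or `C020`; those bands are only attainable by a search that
barely leaves its starting point. We report the recovered values as
computed and flag the gauge in the parameter tables' interpretation here
rather than regularizing the cost toward the initial guess, which would
change the published cost definition.

## What the generator does and does not emulate

The phantom emulates the geometry (22 cm sphere, polar craniotomy cap),
the loading scheme, the landmark placement near the exposure, the 10+10
split and the noiseless inverse-crime design of the published simulation.
It does not emulate: patient-specific geometry and tumor substructure
(meshes built from segmented MRI), CSF drainage and gravity, true
viscoelastic transients, landmark-picking error (available via
`noise_sigma` but zero in the study conditions), or any independent
ground-truth physics — passing recovery here demonstrates correctness of
the solvers and the estimation loop under the model's own assumptions, not
clinical accuracy. Constant-strain tetrahedra also lock volumetrically
near incompressibility: with the default `kappa_vol` the nonlinear
phantom's deformation peaks well below a millimeter, so nonlinear effects
stay mild at the study's load level.

## Numerical choices, degenerate inputs

- Tolerances: linear residual 1e-8 (CG 1e-10); Newton relative residual
  1e-8, max 50 iterations per load step, 6 halvings; point location snaps
  within 1e-3 m and accepts barycentric coordinates down to −1e-10.
- Tie-breaks: point location picks the tetrahedron maximizing the minimum
  barycentric coordinate; outside-but-near points are clamped and
  renormalized (flagged `snapped`).
- Degenerate inputs raise typed errors: non-positive tet volumes, missing
  `FIXED` region (floating structure), empty exposed center, all-cap-nodes
  constrained, non-SPD strain states, triangle-only or mixed-cell mesh
  files, missing label arrays.
- Determinism: the phantom generator is fully deterministic; sampling,
  noise and perturbation draw from seeds derived from the experiment seed,
  and RNG state is restored after each use.

## Known limitations

- Constant-strain tetrahedra are first-order and lock near
  incompressibility; mixed or higher-order elements are out of scope.
- The exposed-center force is a resultant distributed by area weights; the
  published work fixes only the total force, not its distribution.
- The cap's angular size is not stated in the published study; defaults
  are placeholders (10°/25°), configurable per run.
- Recovered absolute stiffness values carry the gauge freedoms described
  above; only `nu`, force/stiffness ratios and relaxation-scaled products
  are true measurements.
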