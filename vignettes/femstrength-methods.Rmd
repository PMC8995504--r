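---
title: "QCT-based finite element femoral strength: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QCT-based finite element femoral strength: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

femstrength estimates proximal femoral strength from quantitative computed
tomography (QCT) and relates it to clinical covariates the way
musculoskeletal QCT-FE studies do: a calibration phantom maps scanner
Hounsfield units (HU) to bone density, empirical power laws map density to
material properties, the segmented bone volume becomes a voxel hexahedral
finite element model loaded in compression through PMMA pads, and the
reaction force at 4% nominal compressive deformation is reported as
femoral strength (FS). A companion statistics layer reproduces the
small-sample workflow used to find predictors of FS in diabetic and
control cohorts. This vignette records the models, the numerical choices
and their rationale, and what the synthetic-data generators do and do not
emulate.

## Density calibration

A calibration phantom with inserts of known calcium-hydroxyapatite
(CaHA)-equivalent density (defaults 0.05, 0.1 and 0.2 g/cm^3) is scanned
with the subject. `fit_calibration()` regresses the known insert densities
on the mean HU inside each insert ROI by ordinary least squares and
reports the line with its r^2. The ROI statistic is the mean, the standard
densitometry choice. `hu_to_apparent()` applies the line voxelwise and
clamps negative calibrated densities (air, soft tissue, noise) to zero,
counting the clamped voxels; whether to clamp is a genuine open choice,
and the count is surfaced so users can audit it. The calibration line is
taken to map HU directly to apparent density — i.e. the CaHA-equivalent
insert density is treated as apparent density. Scanner-specific
CaHA-to-apparent conversions exist, but none is part of the method being
modelled, and inventing constants would be worse than documenting the
identity default.

Ash density follows the affine conversion
`rho_ash = 1.22 * rho_apparent + 0.0526` (g/cm^3), applied elementwise by
`apparent_to_ash()`.

## Material laws and binning

`elastic_modulus()` and `yield_strength()` implement the piecewise
empirical laws for femoral bone:

| rho_ash (g/cm^3) | E (MPa) | sigma (MPa) |
|---|---|---|
| 0 | 0.001 | 0 |
| (0, 0.27] | 33900 rho^2.2 | 137 rho^1.88 (rho < 0.317) |
| (0.27, 0.6] | 5307 rho + 469 | 114 rho^1.72 (rho >= 0.317) |
| > 0.6 | 10200 rho^2.01 | — |

with Poisson's ratio 0.4 for all bone. The adjacent branches agree to
within 0.1% at 0.27 and 0.6 and within 0.05% at 0.317, so the laws are
effectively continuous; breakpoint membership follows the printed
inequalities. The 0.001 MPa value at exactly zero density is applied as a
global floor: the low-density power branch crosses it near
rho_ash = 4e-4, and the floor both keeps the law non-decreasing and keeps
every element stiffness matrix non-singular.

`bin_materials()` discretizes the ash-density range observed over the
bone mask into 120 equal-width bins (the "120 kinds of materials"
convention) and evaluates both laws at each bin midpoint. Equal-width
binning over the observed range and the midpoint representative are our
documented choices where the convention is silent; the midpoint is
unbiased for the linear branch and nearly so for the smooth power
branches at 120-bin resolution. `n_bins = Inf` requests exact per-element
evaluation, which the acceptance suite uses to verify that 120 bins
change the computed strength by under 2%.

## Meshing and boundary hardware

`build_mesh()` converts bone voxels to 8-node hexahedra, one element per
voxel, at a default element size of 1.5 mm; coarser or finer lattices are
produced by integer box-averaging or refinement. Only the largest
6-connected component is kept (stray islands are counted and dropped) so
the stiffness matrix cannot decouple. Node sharing on the lattice makes
the mesh conforming by construction.

`attach_pads()` models the PMMA pads (E = 2500 MPa, nu = 0.3, no yield)
used to transmit load in compression tests. A pad fills the space between
the local bone surface and a flat platen plane, `pad_thickness` layers
(default 2) beyond the bone extreme, over the columns whose surface lies
within `pad_span` layers (default 3) of that extreme. Pad extent and
thickness are not standardized anywhere, so both are configurable; the
defaults give full-footprint flat pads on a flat-cut shaft and a
head-conforming cap superiorly. The tie constraint between pad and bone
is realized as node merging, which for conforming voxel lattices is
kinematically identical to a software tie and exactly testable.

## The compression solve

`solve_compression()` drives the top pad surface down by
`0.04 * femoral_height` in 20 equal displacement steps, with the bottom
pad surface fully clamped. Femoral height is measured over bone only
(pads excluded), since the deformation measure is compressive
displacement divided by femoral height; pad compliance therefore lowers
the nominal bone strain slightly, which is visible in the reaction
history rather than hidden. The driven surface prescribes only the z
displacement (platen-on-pad analogy); `top_clamped = TRUE` gives the
fully clamped alternative, and `bottom_mode = "roller"` gives
frictionless bottom support, which the analytic column oracles need.

The material model is small-strain isotropic elasticity with von Mises
perfect plasticity and associative radial-return mapping. Only E, nu and
a yield stress are available from the material laws — no hardening
modulus — so perfect plasticity is the minimal faithful closure.
Geometric nonlinearity is off: 4% nominal strain under small-strain
theory is the usual QCT-FE convention. Integration uses 2x2x2 Gauss
points and one material per element.

Numerics: each step solves equilibrium by a damped Newton iteration. The
algorithmically consistent elastoplastic tangent decomposes as
`kappa * J + 2 mu beta * P_dev - c * n n'` (volumetric part, radially
scaled deviatoric part, rank-one flow-direction dyad), which is what
makes assembly fast in vectorized R: the first two pieces contract
against constant per-Gauss-point 24x24 blocks, and only the dyad needs
per-element vectors. The dyad is regularized by `zeta = 1e-6` (a tiny
pseudo-hardening visible only to the iteration operator, never to the
residual) because the exact perfect-plasticity tangent is singular along
the flow direction at the limit load. A backtracking line search damps
the Newton step — the elastic-plastic residual is only piecewise smooth
and the undamped step can overshoot when the active plastic set flips.
Linear systems are solved by sparse Cholesky (CHOLMOD via Matrix), with
the symbolic factorization computed once and reused across numeric
refactorizations, and the factorization itself reused across iterations
and steps while it still reduces the residual by at least 30% per
iteration; a dense direct path exists for small meshes and serves as the
reference in the solver-equivalence tests. Convergence is declared at a
relative residual of 1e-6 against the constraint-force norm. Each step
starts from a secant predictor (the previous step's converged increment),
which makes purely elastic steps free.

Reported invariants: global equilibrium (z-components of internal force
sum to ~0 relative to the reaction), external work versus stored energy
in the elastic regime, and the maximum post-return von Mises overshoot
(zero to rounding by construction).

## Synthetic data

`generate_femur_volume()` builds a parametric proximal-femur stand-in —
shaft cylinder, neck frustum, head sphere, aligned with the z loading
axis — with a dense cortical shell (apparent density 1.0-1.8 g/cm^3)
grading into a softer trabecular interior (0.1-0.6 g/cm^3) through a
distance-to-surface transition zone. The blend makes the density range
continuous, which is both more realistic than a two-level field and
necessary for all 120 material bins to be occupied. HU synthesis is a
single global affine map (default 600 HU per g/cm^3, zero intercept —
the scanner relation is free to choose, and any affine map is equivalent
under recalibration) plus i.i.d. Gaussian noise; beam hardening and
scatter are not modelled. The default grid is 48 x 48 x 96 voxels at
1.5 mm — a desk-scale emulation of clinical 512 x 512 / 0.625 mm scans
that keeps an FE solve in minutes. All randomness flows through one
integer seed per call, and fixed seeds give bit-identical volumes.
A `"column"` preset generates the uniform rectangular column used by the
analytic FE oracles.

What passing tests on these volumes do *not* show: performance on real
anatomy (no anteversion, no greater trochanter, no cortical thinning
maps), robustness to segmentation error (the ground-truth mask is known),
or scanner physics. They do show that every algorithmic stage —
calibration, conversion, binning, meshing, assembly, plasticity,
reporting — is correct on inputs where the right answer is known.

`generate_cohort()` draws two groups (diabetic arm and controls; defaults
n = 10 and 8, the published study sizes) from a multivariate normal over
seven covariates with group-specific means (diabetics: higher HbA1c, BMI
and strength-relevant density scores, lower P1NP) and a shared
correlation structure (pentosidine rising with age and C-peptide, T score
falling with age). Strength is each group's linear predictor — by default
the published reference coefficient sets of
`reference_strength_models()` — plus Gaussian noise (default 400 N,
chosen to land the adjusted R^2 of the best models near the reported
~0.93-0.96 range). The generating coefficients ride along as an
attribute, so recovery tests compare fitted against known values.

## Cohort statistics

`mann_whitney()` and `spearman_cor()` wrap the standard tests with an
explicit small-sample policy — exact enumeration p-values whenever the
sample is small and tie-free (combined n <= 20 for the rank-sum test,
n <= 9 for the correlation), mid-rank approximations otherwise — and
always record which path was taken, because at n = 10 vs 8 the
approximation error is not negligible. The test suite checks the exact
paths against brute-force enumeration written independently of the
implementation.

`fit_ladder()` fits the hierarchical regression ladder (base predictor,
then one addition per rung), reporting unstandardized coefficients with
95% t-intervals, standardized coefficients from z-scored variables,
adjusted R^2, and an improvement flag per rung; rank-deficient or
saturated rungs are reported as unfittable rather than silently dropped,
mirroring how such rungs appear as missing entries in published model
tables. `screen_collinearity()` formalizes the usual pre-step of dropping
one of a highly correlated predictor pair (default |r| > 0.8) in favour
of the one more correlated with strength — the femoral-BMD-versus-T-score
situation. Tests are two-sided at alpha = 0.05 with no multiplicity
correction, matching the workflow being modelled. `reference_ladder()`
ships the published ladder ordering as a preset, since the entry criteria
for "potentially significant" predictors are inherently ad hoc and
therefore user-configurable.

`predict_strength()` evaluates a fitted or published linear model;
with all covariates at zero it returns the model constant (29240.848 N
for the diabetic model, 9584.833 N for the control model), which the
acceptance suite uses as a worked example.

## Problem sizes and limitations

The test suite runs its FE oracles on columns of tens of elements, the
pipeline properties on a 24 x 24 x 48 femur (~2300 elements), and the
acceptance binning comparison on the full 48 x 48 x 96 default femur
meshed at 3 mm (~2600 elements; the binning effect being measured is
element-size independent, and coarser test meshes are the stated escape
hatch of the mesher's design). A full 1.5 mm mesh of the default femur
(~16000 elements) solves in tens of minutes and is left to interactive
use. These sizes were chosen so the whole suite completes in minutes
while still exercising every code path. Known limitations: no tension/compression asymmetry,
anisotropy, strain-rate effects or site-specific laws (none appear in
the material model being implemented); no sideways-fall loading or
damage/softening; small-strain kinematics only; voxel meshes have
stair-stepped surfaces, so stress fields near the boundary are accurate
only in an averaged sense — the reported strength is a surface integral
and is much less sensitive to this than pointwise stresses.
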