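---
title: "Phantom-based fetal brain morphometry and cohort comparison: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based fetal brain morphometry and cohort comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalfold)
```

## What the package computes

`fetalfold` re-implements, as a reusable and tested pipeline, a morphometric
analysis of in-utero fetal brain MRI across two enrollment epochs: tissue
volumetry from labeled volumes, extraction of the gray-white junction
surface, three cortical folding metrics (surface area, local gyrification
index, sulcal depth), and a battery of generalized estimating equations
(GEEs) comparing cohorts of mothers scanned up to twice during pregnancy,
with maternal-distress stratification and false-discovery-rate control.

Real fetal MRI and the associated cohort records are not distributable, so
the package ships a synthetic-data stage with two faces:

* `make_phantom()` renders labeled brain phantoms with *known analytic
  geometry*, so every geometric operation can be tested against a closed
  form; and
* `simulate_cohort()` draws whole cohorts with the statistical structure the
  analysis assumes (repeated scans, growth with gestational age, cohort
  effects, bounded distress scores), with every generating parameter
  recorded as ground truth on the scan row.

## The phantom: a folded sphere with known volumes

The white-matter core boundary is a radially perturbed sphere,

$$ r(\theta, \varphi) = R\,\bigl(1 + A \sin(f\theta)\sin(f\varphi)\bigr), $$

wrapped in a cortical shell of constant thickness $t$. The product-of-sines
perturbation is smooth, convex at $A = 0$, and gives gyrification a single
controllable knob with known qualitative behavior. Ellipsoidal accessory
structures (deep gray matter, paired ventricles and hippocampi inside the
core; cerebellum and brainstem below it) are placed mutually disjoint, so
every structure volume has a closed form (`phantom_analytic_volumes()`):
the odd angular moments of the perturbation vanish, leaving
$V_{\text{core}} = \tfrac{4}{3}\pi R^3 (1 + 3A^2\,\mathbb{E}[s^2])$, shell
and ellipsoid volumes exactly as written. An optional radial pit with a
$\cos^2$ profile and an exact planar rim provides a sulcal-depth oracle:
the pit bottom sits $d - R(1-\cos\sigma)$ from the convex hull by
construction.

The parcellation divides the solid angle into eight cortical sectors per
hemisphere (four lobes as equal front-to-back wedges, cingulate at the
superior pole, insula/corpus callosum at the inferior pole) plus deep gray
matter and ventricles - ten regions per hemisphere, with exact ground truth
for every surface vertex. Hemispheres split on the mid-sagittal plane;
points exactly on it belong to the left hemisphere by convention.

## Surface extraction: why marching tetrahedra plus Taubin smoothing

`extract_junction_mesh()` contours the binary inside-indicator at level 0.5
with marching tetrahedra (the six-tetrahedron Kuhn decomposition, a
conforming split, so the surface is watertight whenever the structure stays
off the grid boundary). Vertices live in the world frame
`index * spacing` with no affine rotation, which keeps the phantom oracles
exact.

Two numerical facts drove the smoothing design, both measured during
development:

* the raw binary isosurface of a digitized sphere carries a ~8-9% *positive*
  area bias (staircase micro-faceting), independent of resolution;
* Gaussian smoothing of the indicator field removes that bias but rounds the
  edges of a cuboid, losing 4-9% of its area at practical sigmas - the loss
  scales with the smoothing radius and is a property of the field, not of
  the mesh.

Taubin smoothing of the extracted mesh (alternating $\lambda = 0.5$,
$\mu = -0.53$ steps, 60 iterations by default) resolves both: it is
shrink-free, planar regions stay planar, and the staircase dimples flatten
out. Measured at 1 mm spacing the sphere area error is +2.7% and the 20 mm
cuboid error is -2.5%; both shrink when the grid is refined to 0.5 mm.
Gaussian field smoothing remains available (`smooth_sigma`), default off.

## Folding metrics

**Surface area** credits each triangle to the majority region of its three
vertices (ties go to the lowest-index vertex) and sums per lobe.

**Local gyrification index.** For a vertex $v$, the numerator is the summed
per-vertex associated area (one third of incident triangle areas) over all
vertices within geodesic distance $\rho$ of $v$; the denominator is the
convex-hull area inside the Euclidean ball of radius $\rho$ centered at
$v$'s nearest point on the hull. Three conventions had to be fixed:

* *Patch radius* $\rho$: the method family never states it; fetal brains are
  small, so the default is 15 mm (config; all tests pin it explicitly).
* *Geodesic definition*: shortest paths over a chord graph linking vertices
  within `chord_ring = 4` mesh edges. The plain edge graph (ring 1)
  overestimates surface distance by ~7% on average on contoured meshes
  (direction-dependent dispersion), which alone pushes convex-surface LGI
  down to ~0.85; 3-ring chords bring the mean within ~0.5% but leave a
  dispersion tail that dents a handful of vertices below 0.95, while 4-ring
  chords give convex-phantom LGI in [0.96, 1.02] for every vertex at no
  extra runtime. Chords stay within four mesh edges of the surface, so they
  cannot tunnel across sulci at the fold scales the phantom generates.
* *Hull for LGI vs depth*: LGI uses the hull of the whole surface; sulcal
  depth uses each hemisphere's own hull. A hemisphere hull is bounded by a
  flat mid-sagittal wall, and for vertices within a patch radius of that
  wall the extra wall area inflates the LGI denominator by up to ~50% - a
  cut artifact, not cortical envelope. Depth, by contrast, is defined
  per-hemisphere so that one hemisphere's folds are never measured against
  the other's envelope.

The hull-side patch area is measured by midpoint-subdividing hull triangles
(default target edge 1 mm) and summing sample areas inside the ball; the
hull correspondence via the nearest hull point is the simplest reading of
"the corresponding area on the hull" and is a documented convention - the
monotonicity properties do not depend on it.

**Sulcal depth** is the exact point-to-triangle minimum distance from each
vertex to its hemisphere's hull (never vertex-to-vertex, which would
overestimate depth between hull vertices).

## The cohort simulator: the stated world

Defaults mirror the study's printed structure: 137 pre-pandemic and 65
pandemic mothers, 33%/42% scanned twice, gestational age truncated-normal
on 16.7-39.1 weeks (mean 29.5, sd 6.5 - the printed medians and IQRs are
reproduced to within sampling noise), second scans 6-12 weeks later, 52%
male fetuses, ~14% of mothers without distress scores, and ~26% of scans
without folding outcomes (failed surface reconstruction).

Tissue volumes follow exponential growth curves anchored to the printed
adjusted means near 30.4 weeks (e.g. white matter ~99 cm^3) with
field-plausible weekly rates (0.07-0.135); folding features grow linearly
(global surface area ~160 cm^2, LGI ~1.28, depth ~1.6 mm at the anchor).
These anchors are the published cohort-level values; the *rates* and the
noise structure (subject-level random intercept plus residual, magnitudes
chosen once at the scale of the printed standard errors) are the package's
own choices, stated here and in `?cohort_spec`, not inferred from data.
Distress scores are truncated normals inside the published scale bounds
(SSAI/STAI 20-80, PSS 0-40, EPDS 0-30) with pandemic-epoch shifts in stress
and depression; the source reports only medians and thresholds, so the
distributional detail is config, not inference.

Cohort effects are *additive* on each outcome, and the generating values are
stored with the data, so parameter-recovery tests need no re-derivation.
What a green simulation test establishes is therefore: the estimator
recovers known additive effects under the assumed correlation structure,
missingness, and growth curves. It does not establish anything about motion
artifacts, segmentation error correlated with gestational age, cohort
differences in scan timing, or any other feature of real fetal MRI the
generator does not emulate.

A deliberate feature of the stated world: volumes grow exponentially with
gestational age but the GEE adjusts for age *linearly*, exactly as the
original analysis does. The lack-of-fit inflates residual spread (robust
standard errors absorb it) but leaves the cohort contrast unbiased because
epoch is independent of age at scan; the recovery and calibration tests
pass through this misspecification on purpose rather than simulating a
conveniently linear world.

## The statistical engine

`fit_gee()` implements Gaussian identity-link GEE with an exchangeable
working correlation (Liang-Zeger moment estimator, clusters = mothers,
cluster size at most 2), iterated to a 1e-8 coefficient tolerance, with the
robust sandwich covariance and two-sided Wald tests. Exchangeable is the
canonical choice for at-most-two scans; `corstr = "independence"` is
available and provably identical on singleton clusters. The implementation
was verified against an independent reference implementation to eight
decimals on a frozen fixture (coefficients, robust SEs, and the working
correlation itself); singleton-cluster fits reduce to ordinary least squares
exactly.

Least-squares means evaluate the fitted model at cohort 0/1 with every
other covariate at its sample mean (factors at sample proportions);
interaction columns involving the grouping variable are rebuilt as
(mean of the partner) x (group value). Under the identity link the LS-mean
difference equals the cohort coefficient identically, which the tests
assert at 1e-10. Fetal sex enters with female as the referent level.

`enumerate_models()` expands the full battery - 12 distress models (step 1),
90 = 18 + 72 brain-outcome models (step 2), 36 = 24 + 12 stratified models
(step 3), 72 distress-association, 12 age-by-cohort interaction, 180
sensitivity, 36 laterality, 72 parental models - deterministically and
order-stably, each specification carrying its FDR family (6 tissues, 4
lobes per feature, 3 global features). The step-3 measure list is an
explicit input (default PSS and EPDS, the measures the step-1 battery
flags), never re-derived implicitly, so counts are stable. Benjamini-
Hochberg q-values are computed within each family; `p < 0.05` and
`q < 0.05` are flagged separately, mirroring the dual marking in the
source tables. Missing distress scores drop a scan from distress-adjusted
models only (complete case); whether stratification should use per-scan or
worst-scan scores for twice-scanned mothers is unstated in the source, and
this implementation stratifies per scan.

Demographic comparisons use Shapiro-Wilk screening, exact-when-possible
Wilcoxon-Mann-Whitney, and Pearson chi-square without continuity
correction; inter-rater agreement uses the two-way random-effects
absolute-agreement single-measure ICC; growth curves are exponential
(log-scale least squares) for volumes and linear for folding features,
drawn in the report figures from the same fitted objects.

## Numerical choices and degenerate inputs

* GEE: rank-deficient designs, fewer than two clusters, and non-convergence
  are explicit errors; constant outcomes short-circuit to the exact answer.
  The exchangeable correlation estimate is clamped inside
  (-1/(max cluster size - 1), 1).
* Convex hulls: quickhull with a scale-aware tolerance (1e-10 x bounding
  diagonal); collinear or coplanar inputs are errors, as is an open horizon
  (numerically degenerate input). Hull containment is tested at 1e-6 mm.
* Mesh cleanup: exact vertex welding on grid-edge keys (no tolerance
  needed), zero-area triangles dropped, closedness asserted (every edge in
  exactly two triangles), largest component kept per hemisphere with the
  discarded area reported.
* LGI: the patch radius must exceed three mean edge lengths (error
  otherwise); an empty hull patch (radius below the hull sampling) is an
  error rather than an NA.
* Ties: triangle-majority region ties go to the lowest-index vertex;
  nearest-label ties go to the smallest label id; scores exactly at a
  distress threshold are "low" (strict inequalities throughout).
* Truncated-normal draws use the inverse CDF; an interval carrying less
  than 1e-12 of the parent mass is rejected as an impossible truncation.

## Known limitations

* The phantom's folding is a global sinusoidal pattern, not fetal
  sulcation; it validates *operators*, not biological folding statistics.
* Graph geodesics (even chord-augmented) are not exact polyhedral
  geodesics; the residual ~0.5% metric error is second-order for the test
  meshes but would matter for patch radii near the mesh edge length.
* The hull-patch correspondence (Euclidean ball at the nearest hull point)
  is one of several conventions in the literature; LGI *levels* depend on
  it, monotonicity in folding amplitude does not.
* No small-sample GEE corrections, no mixed-effects alternative, no
  imputation of missing distress scores - matching the scope of the
  original analysis.
* Numeric agreement with the source's data tables is out of reach by
  construction (no raw data are distributable); the acceptance surface is
  the printed bookkeeping (model counts, thresholds, acquisition
  arithmetic) plus the property-based oracles above.
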