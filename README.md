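# fetalfold

Fetal-brain phantom morphometry and cohort comparison in R.

`fetalfold` is for researchers who quantify in-utero brain development from
labeled fetal MRI volumes and compare cohorts of mothers scanned repeatedly
during pregnancy. Raw fetal MRI is rarely shareable, so the package pairs the
measurement pipeline with a synthetic-data stage: analytic brain phantoms with
known geometry, and simulated cohorts whose generating parameters are recorded
as ground truth. Every operator is tested against a closed form or an
independent oracle.

The pipeline:

1. **Phantoms / cohorts** — `make_phantom()` digitizes a folded-sphere brain
   (white-matter core boundary `r(θ,φ) = R(1 + A sin fθ sin fφ)`, cortical
   shell, disjoint ellipsoidal structures) into segmentation + parcellation
   label volumes; `simulate_cohort()` draws two-epoch cohorts (truncated-normal
   gestational ages on 16.7–39.1 weeks, repeat scans, distress scores inside
   the published scale bounds, configurable additive cohort effects).
2. **Volumetry** — `tissue_volumes()`: voxel count × voxel volume, reported in
   cm³; `in_plane_resolution(320, 256)` reproduces the 1.25 mm acquisition
   arithmetic.
3. **Surface** — `extract_junction_mesh()` contours the gray–white junction
   (marching tetrahedra + shrink-free Taubin smoothing), `assign_regions()`
   maps vertices to the 10 regions × 2 hemispheres, `convex_hull_mesh()`
   builds the reference envelope.
4. **Folding metrics** — per-vertex local gyrification index
   (geodesic-patch area over hull-patch area; LGI ≈ 1 on a convex brain) and
   sulcal depth (exact point-to-triangle distance to the hemisphere hull),
   aggregated per lobe by area-weighted means.
5. **Statistics** — `fit_gee()`: Gaussian GEE with exchangeable working
   correlation and robust (sandwich) covariance for mothers with up to two
   scans; `ls_means()`, `enumerate_models()` + `run_battery()` for the full
   model battery (12/90/36/72/12/180/36/72 models) with Benjamini–Hochberg
   q-values within outcome families; Wilcoxon–Mann–Whitney, chi-square,
   Shapiro–Wilk, ICC(A,1), exponential/linear growth fits.

## Worked example

```r
library(fetalfold)

# simulate a cohort with a planted -5 cm^3 white-matter deficit
spec <- cohort_spec(n_subjects = c(pre = 100, pandemic = 100),
                    effects = list(volumes = c(wm = -5)), seed = 7)
scans <- simulate_cohort(spec)
fit <- fit_gee(scans, vol_wm ~ cohort + ga_mri_weeks + sex, id = "subject_id")
tidy(fit)
#> # A tibble: 4 × 5
#>   term         estimate std.error statistic   p.value
#>   <chr>           <dbl>     <dbl>     <dbl>     <dbl>
#> 1 (Intercept)  -173.        7.65   -22.7    8.41e-114
#> 2 cohort         -4.27      2.04    -2.10   3.60e-  2
#> 3 ga_mri_weeks    9.46      0.243   38.9    0
#> 4 sexmale         0.103     2.03     0.0507 9.60e-  1
ls_means(fit)
#> # A tibble: 2 × 3
#>   group lsmean    se
#>   <dbl>  <dbl> <dbl>
#> 1     0   104.  1.46
#> 2     1   100.  1.41
```

The cohort coefficient is the adjusted pandemic–pre-pandemic difference: here
−4.3 cm³ (robust SE 2.0) against a planted −5, and the LS-means are the
cohort means at the sample's gestational-age and sex mix — their difference
equals the coefficient exactly under the identity link. A full run
(phantom rendering → volumetry → surface → folding metrics → batteries →
figures) is one call:

```r
cfg <- pipeline_config(seed = 1)
run_pipeline(cfg, "run1")        # cohort.csv, measured_features.csv,
                                 # stats_*.csv, lsmeans.csv, figures/
```

A thin CLI wrapping these functions ships in `inst/scripts/fetalfold`
(verbs `simulate`, `volumes`, `surface`, `features`, `stats`, `report`,
`run`).

## Acceptance script

`scripts/acceptance.R` re-runs the package end to end from scratch — cohort
simulation with the published effect-size magnitudes, phantom rendering,
surface extraction, folding metrics, the step-1/2/3 GEE batteries with FDR,
LS-means and the report — under a given seed:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The study's subject-level results are only available on request, so there are
no numeric reproduction targets; the script exercises the full computation and
writes its report to `--out`.

## Documentation

`vignettes/fetalfold-methods.Rmd` documents the models and every design
choice: the phantom's closed-form volumes, why surface extraction uses
marching tetrahedra plus Taubin smoothing, the geodesic and hull conventions
behind the gyrification index, what the cohort simulator does and does not
emulate, and the GEE implementation details.
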