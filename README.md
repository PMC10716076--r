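# jomorph

Landmark-based cranial morphometrics for fragmentary archaeological
samples, built around the analysis of regional diet and population-history
signals in prehistoric Jomon forager crania from the Japanese Archipelago.
It is aimed at biological anthropologists and geometric morphometricians
who need the full chain — from TPS/CSV landmark files with missing points
to permutation shape statistics and spatial correlograms — as tested,
scriptable R functions rather than a GUI workflow.

## What it computes

* **Missing-landmark imputation by midline mirroring.** Each specimen's
  sagittal plane is estimated by least squares from its own midline
  landmarks and complete bilateral pairs (closed-form eigen solution); a
  missing landmark whose bilateral partner is preserved is replaced by the
  partner's reflection. Imputation is attempted only where fewer than four
  landmarks are missing.
* **Generalized Procrustes analysis.** Configurations are centred, scaled
  to unit centroid size CS = sqrt(Σᵢ ‖xᵢ − x̄‖²), and iteratively rotated
  to the consensus; shapes are then projected orthogonally into the
  tangent space at the consensus so Euclidean multivariate statistics
  apply.
* **Permutation shape statistics.** Shape-on-size regression
  (Goodall-style r² = SS_model/SS_total against ln CS), permutation MANOVA
  (Goodall-type F = (SSB/(g−1))/(SSW/(n−g)) with label permutation), PCA,
  canonical variates analysis with PCA regularization, and pairwise
  Procrustes-distance tests between group mean shapes.
* **Relative bite force.** BF = (TCS·t + MCS·m) / Mo, where TCS and MCS
  are temporalis and masseter centroid sizes, t and m the lever arms from
  each muscle centroid to the temporomandibular joint, and Mo the moment
  arm from the TMJ to the M2 bite point; group comparison runs
  Shapiro–Wilk, Brown–Forsythe Levene, then Welch or classical one-way F
  and Tukey HSD.
* **Spatial correlograms.** Moran's I = (n/W)·Σᵢⱼ wᵢⱼ(xᵢ−x̄)(xⱼ−x̄) / Σᵢ(xᵢ−x̄)²
  with binary distance-class weights over 100-km half-open classes of
  great-circle distance, with two-sided permutation p-values around the
  null expectation −1/(n−1).
* **Synthetic data with ground truth.** A simulator generating annotated
  skull-landmark datasets (group effects, allometry, spatial clines,
  landmark noise, MCAR missingness) over the bundled 16-site / 5-diet-group
  Jomon study structure, for parameter-recovery testing.

## Worked example

```r
library(jomorph)

ds  <- simulate_study(c("neurocranial", "biteforce"), seed = 42,
                      missing_rate = 0.03)
cfg <- pipeline_config(sets = c("neurocranial", "biteforce"),
                       n_perm = 999, seed = 42)
rep <- run_pipeline(ds, cfg)

rep$preliminary$neurocranial$size_regression
#> Shape ~ ln(CS): F(1, 65) = 1.452, r2 = 0.0219 (2.19%), p = 0.187 (999 perms)
rep$diet$neurocranial$manova
#> Permutation MANOVA: F(4, 62) = 22.487, p = 0.001 (999 perms)
rep$diet$neurocranial$cva
#> CVA: 4 canonical axes; % group differentiation: 46.55, 35.60, 12.52, 5.33
rep$diet$biteforce
#> Classical one-way test: F = 2.1411 (df 3, 37), p = 0.1116; Levene p = 0.5785
#> dropped (n < 2): ICH
```

The regression line says ~2% of neurocranial shape variation in this
simulated sample tracks log centroid size (not significant at the default
simulated allometry). The MANOVA and CVA recover the simulated
between-diet-group shape differences (CV1 carries 46.6% of group
differentiation). The bite-force comparison drops the single-specimen ICH
group, finds homogeneous variances (Levene p = 0.58, so the classical
branch), and no significant group difference. `rep$spatial` holds Moran's
I correlograms of site-mean centroid size and PC1/PC2 against the 100-km
distance classes, and `pipeline_config(out_dir = ...)` writes every table
as CSV.

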