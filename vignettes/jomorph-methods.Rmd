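---
title: "Methods: landmark morphometrics for fragmentary crania"
author: "jomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark morphometrics for fragmentary crania}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jomorph)
```

# The analysis problem

Archaeological cranial samples are fragmentary: different specimens
preserve different landmarks, so every analysis runs on a different
subset of individuals. `jomorph` implements the standard chain used to
study such samples — here organised around a 16-site sample of
prehistoric Jomon foragers grouped into five regional diet categories
(HOK, NEH, CCH, ICH, SWJ) — as composable, seeded, tested functions:
imputation of missing bilateral landmarks, Procrustes superimposition,
permutation shape statistics, a landmark-based bite-force score, and
spatial autocorrelation of site-level morphology.

# Landmark sets

Five built-in sets mirror the usual subdivision of a cranial sample:
craniofacial (37 landmarks), facial (22, a named subset of the
craniofacial set), neurocranial (9), temporalis region (6), and a
bite-force set. Each landmark carries a laterality label and, where it
has a mirror twin inside the set, a bilateral partner index. Two points
deserve comment.

First, the bite-force set stores 28 points: 12 true landmarks and 14
semilandmarks describing the temporalis (indices 2–4, 9–12, 16–26) and
masseter (1, 5–8, 13–15) muscle outlines, plus the temporomandibular
joint (27) and the M2 bite point (28) as separate lever-arm endpoints.
Keeping the TMJ and bite point outside the muscle index sets makes the
role map unambiguous and lets the disjointness be validated. The
semilandmarks contribute to muscle centroid sizes only; they are never
slid and never enter shape analyses.

Second, lateral landmarks without a partner are allowed. The
neurocranial, temporalis and bite-force sets are digitised on one side
of the cranium, so their lateral points have no within-set mirror twin;
mirror imputation simply does not apply to them, and specimens missing
such points are excluded from the affected analysis rather than
repaired.

# Midline estimation and mirror imputation

The symmetry plane of a specimen is estimated from its own landmarks.
Writing C for the scatter matrix of the on-plane evidence (present
midline landmarks and the midpoints of complete bilateral pairs, about
their mean) and D for the sum of outer products of pair difference
vectors, the least-squares plane normal is the eigenvector of C − D with
the smallest eigenvalue; the plane passes through the mean of the
on-plane points. This is exact for perfectly symmetric configurations,
equivariant under rigid motion, and deterministic (the eigenvector sign
is fixed so its first non-negligible component is positive). With no
complete pair and fewer than three non-collinear midline points the
plane is not identifiable and estimation errors out.

Imputation replaces each missing landmark whose partner is present by
the partner's reflection through that plane and flags it; the flag is
carried into the completeness report, but downstream statistics treat
imputed points as ordinary data (nothing in the analysis chain
down-weights them). Imputation is only attempted when a specimen is
missing at most `max_missing = 3` landmarks — "fewer than four" read
strictly — because the midline itself degrades as landmarks disappear.
Specimens over the threshold are returned unchanged and flagged
excluded. Midline landmarks and pairs missing on both sides are never
imputed.

The least-squares objective above is a documented choice: the original
desktop tools in this field do not publish the exact plane-fitting
objective they use. On symmetric inputs any reasonable objective gives
the same plane, which is what the exactness tests pin down.

# Superimposition and tangent space

Generalized Procrustes analysis centres each configuration, scales it to
unit centroid size (size is removed entirely; there is no
partial-Procrustes option in the default path), and iteratively rotates
all configurations to the running consensus, which is recomputed as the
normalised mean shape until it moves by less than 1e-10
(root-summed-squared change; at most 100 iterations, non-convergence is
flagged and a partial result returned). Reflections are forbidden
throughout — side standardisation is preprocessing's job, not the
aligner's.

Shapes are mapped to Euclidean coordinates by orthogonal projection onto
the tangent space at the consensus: with x the vectorised aligned shape
and c the vectorised consensus (both unit norm), the tangent vector is
x − (x·c)c. The consensus maps to zero, the projection is idempotent,
and for shapes close to the consensus the tangent norm agrees with the
Procrustes distance to well under 1%. Between-shape distances use the
full Procrustes distance sin(ρ) (unit-size configurations, optimal
rotation and scale), and output tables label it as such.

# Permutation statistics

With p (shape variables) far exceeding n (specimens), classical
parametric MANOVA statistics are singular, so all group and regression
tests are permutation tests built on summed squared tangent deviations:

* shape-on-size regression: r² = SS_model/SS_total over all shape
  variables against ln CS, F = SS_model/(SS_res/(n−2)), p by permuting
  the predictor (10,000 permutations by default, p estimated as
  (b+1)/(m+1));
* group tests: Goodall-type F from between- versus within-group sums of
  squares, p by permuting labels; outputs are labelled "permutation
  MANOVA";
* pairwise tables: full Procrustes distance between group mean shapes,
  per-pair label permutation, distances below and p above the diagonal in
  exports; single-specimen groups get distances but flagged (NA) p;
* CVA: tangent data are first reduced by PCA to the smallest number of
  axes reaching 95% of variance, capped at n − g, then the
  between/within eigenproblem is solved via a Cholesky symmetrisation;
  axes are scaled to unit pooled within-group variance and oriented
  deterministically. The PCA pre-reduction is this package's documented
  regularisation; the internal handling of the original desktop tools is
  unpublished.

The per-pair permutation of Procrustes distances (rather than a
decomposition of an omnibus statistic) is likewise a documented
resolution of an ambiguity in common practice. All permutation
procedures consume a user seed through one local RNG (restoring the
caller's RNG state), with permutations generated in a fixed documented
order, so every result is reproducible bit-for-bit. Significance is read
at α = 0.05 throughout.

# Bite force

BF = (TCS·t + MCS·m)/Mo is computed from raw millimetre coordinates —
size is the signal here, so bite-force configurations are never
Procrustes-scaled. All lever and moment arms are 3D Euclidean distances
between landmark-derived points (muscle-subset centroid to TMJ; TMJ to
M2). The score is a dimensionless relative quantity on an mm² scale and
is reported for comparison between groups, not converted to Newtons: no
physiological cross-section or muscle-force coefficient is applied. The
group comparison drops groups with fewer than two specimens (recording
them), tests normality per group (Shapiro–Wilk, needs n ≥ 3) and
variance homogeneity (Brown–Forsythe Levene), and uses Welch's F when
Levene rejects at 0.05, the classical one-way F otherwise, with Tukey
HSD post hoc. The branch rule is deterministic given the data.

# Spatial analyses

Geographic distances are haversine great-circle distances on a sphere of
mean radius 6371.0088 km; at the between-site scale analysed here the
difference from ellipsoidal geodesics (< 0.3%) is irrelevant. Site pairs
are binned into half-open 100-km classes [0,100), [100,200), …, up to
the class containing the largest distance; empty classes are retained.
The bundled 16-site matrix yields 17 classes, with the two closest
published site pairs falling in class 1.

Moran's I uses deviations from the plain mean and the
maximum-likelihood (divide-by-n) variance in the denominator, with
binary class-membership weights — not row-standardised, which is the
convention difference to keep in mind when comparing against
row-normalising correlogram tools. Its null expectation is −1/(n−1),
and the permutation p is two-sided around that expectation because both
positive (nearby sites alike) and negative (nearby sites unlike)
autocorrelation are of interest. Within a replicate the same
permutations are shared across classes. Sites without data are excluded
pairwise; classes whose pairs all involve such sites are flagged
undefined, mirroring the dashes of conventional correlogram tables.
Site-level inputs are per-site arithmetic means of centroid size and of
PC1/PC2 scores; PC2 runs through exactly the same code path as PC1.

# The synthetic-data generator

Because no raw landmark data are deposited for the motivating sample,
the package ships a generator whose defaults describe the study
conditions once: the bundled 16-site table (five diet groups, per-site
sample sizes 1–20, 85 specimens, an arc of ~1700 km with synthetic
coordinates — the real site coordinates are unpublished, so only the
published between-site distance matrix is carried as data). Each
specimen is the symmetric template pre-shape plus a per-group tangent
offset (norm 0.03 by default, the order of observed between-group
distances), an allometric direction scaled by centred log size
(calibrated so a designed fraction, default 4.5%, of shape variance
tracks size), an optional spatial cline (default 0: the motivating
analyses found no spatial pattern), and isotropic landmark noise
(default 1 mm); the configuration is scaled to a log-normal centroid
size (sdlog 0.05 about the template size), rigidly moved, and landmarks
are deleted MCAR (default rate 0.05). Effect directions are drawn inside
the proper shape-tangent subspace (orthogonal to scaling, translation
and infinitesimal rotation at the template), so their stated norms
survive superimposition — this is what makes parameter-recovery tests
sharp. All draws come from one seeded stream in a documented order;
identical specs give byte-identical datasets, and the realized effects
are returned as ground truth.

What the generator does not emulate: non-random preservation
(missingness in real crania correlates with anatomy; here it is MCAR
because no alternative mechanism is documented for the motivating
sample), measurement error structure from mixed scanner sources,
asymmetry, age structure, and temporal heterogeneity within sites.
Passing recovery tests therefore demonstrate that the estimators recover
the parameters of this generative model, not that real Jomon data would
behave identically.

# Numerical choices and degenerate inputs

Convergence and identity tolerances follow the field's conventions: GPA
tolerance 1e-10; eigenvector and normal signs fixed deterministically;
degenerate configurations (coincident points, rank-deficient scatters)
raise errors rather than returning garbage; exact fits clamp the
residual sum of squares at zero before forming F (otherwise floating
point can make a perfect fit look infinitely bad rather than infinitely
good). TPS files have no standard missing-value encoding, so a sentinel
(−9999 by default, configurable) marks absent landmarks; CSV uses empty
cells. Units are millimetres throughout; site and specimen identifiers
match case-sensitively and exactly.

# Pipeline and reproducibility

`run_pipeline()` executes the study sequence — impute, subset per
landmark set, GPA, preliminary analyses (shape~lnCS, sex tests, bite
force by sex), diet analyses (MANOVA, CVA, pairwise distances, bite
force by diet), spatial analyses (site summaries, correlograms) —
logging every exclusion decision, including the pooling of sexes when no
shape set shows significant dimorphism. One global seed is hashed with
each stage name to give per-stage seeds, so toggling a stage never
perturbs another stage's randomness; identical configurations produce
byte-identical CSV outputs. Report numbers print at 2–4 decimals but are
stored full-precision.

# Problem sizes in the test suite

The suite exercises the estimators at sizes chosen to balance power
against runtime on a single core: type-I error simulations use 200
replicates of n = 20–30 with 999–1000 permutations; allometry recovery
uses 200 generated studies of n = 60; group-distance recovery 100
two-group studies of n = 30 (99 permutations per test); cline detection
100 transect studies of 8 sites × 5 specimens; the Moran's I
brute-force equivalence is exhaustive for all n ≤ 6. The acceptance
script repeats these computations from scratch under a caller-supplied
seed.

# Known limitations

Semilandmark sliding, TPS/regression-based imputation, Mahalanobis-based
CVA tests, allometry-corrected CVA, Mantel tests, sea-route or
least-cost distances, and 2D data are out of scope. The bite-force
moment arm is a landmark-to-landmark chord rather than a
surface-measured arm, which can differ slightly on strongly curved
crania. Correlogram p-values at small site counts are granular
(999 permutations bound p below at about 0.001), and classes held
together by one or two pairs carry Moran's I values of limited meaning —
the undefined flag marks only the strictly uncomputable cases.
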