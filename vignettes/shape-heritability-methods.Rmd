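---
title: "Methods: vertex-wise shape heritability with shapeherit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vertex-wise shape heritability with shapeherit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapeherit)
```

## Overview

`shapeherit` estimates how much of the person-to-person variability in the
*shape* of subcortical brain structures is attributable to additive genetic
factors, at the resolution of single surface vertices. The pipeline runs in
five stages:

1. **Shape description** — from corresponded surface meshes, two per-vertex
   descriptors: radial distance (mm) and the log surface Jacobian
   determinant; plus gross volume (cm³) per structure.
2. **Genomic relatedness** — variant QC, a genomic relationship matrix
   (GRM), and relatedness pruning, so population subjects can be modelled
   as unrelated.
3. **Heritability estimation** — per vertex: single-GRM restricted maximum
   likelihood (population cohorts) or ACE maximum likelihood (twin
   cohorts), each with a boundary mixture-χ² likelihood-ratio test.
4. **Reliability and reduction** — test–retest ICC maps, PCA of the
   vertex-wise measures, and heritability of component scores.
5. **Localization** — Benjamini–Hochberg FDR flags at `q = 0.05`.

Every stage is exercised end to end on synthetic cohorts with known ground
truth; the generator is first-class, tested code.

## Shape descriptors

Meshes are assumed *corresponded*: each structure has a fixed vertex count
and topology across subjects, so vertex `v` is anatomically matched. The
pipeline does not perform registration; correspondence is its entry
contract (synthetic cohorts have it by construction; real data must supply
it, e.g. from a template-registration pipeline).

**Radial distance** of vertex `v` is its Euclidean distance to the medial
curve of the structure. The curve is fit **once on the template** and held
fixed for all subjects, so between-subject differences in the measure
reflect surface change rather than curve refitting. The medial model is a
simplified construction: vertices are projected on the mesh's first
principal axis, partitioned into equal-width bins, per-bin centroids are
computed and smoothed with a moving average. Two refinement passes
re-estimate each vertex's axial coordinate along the *local tangent* of its
bin (central differences of the smoothed centroids) and recompute the
centroids; this corrects the oblique cross-section cuts that a single
global projection makes on bent structures, and leaves a straight
cylinder's curve collinear with its axis to machine precision. Meshes whose
top-two covariance eigenvalues are too close (spherical objects) are
rejected — the medial curve of a ball is not a curve.

**Log-Jacobian (surface dilation)**: `ln(A_subject(v) / A_template(v))`,
where `A(v)` is the barycentric one-ring area of vertex `v` (one third of
the summed incident triangle areas). An area-based rather than volumetric
Jacobian is used because the quantity of interest is surface dilation; a
subject uniformly scaled by `s` scores `2 ln s` at every vertex, exactly.

**Gross volume** uses the signed-tetrahedron divergence formula on the
closed mesh, reported in cm³; inward-oriented meshes are flipped with a
warning rather than rejected.

Both descriptors are invariant under a common rigid motion of subject and
template (the curve is refit on the moved template), verified to 1e-8 in
the tests.

## Genotype QC and the GRM

Variants are filtered on imputation quality (`Rsq >= 0.5`), minor allele
frequency (`>= 0.01`), Hardy–Weinberg equilibrium (`p >= 1e-6`) and call
rate (`>= 0.95`). The GRM is

`K = W W' / M`, `w_ij = (x_ij - 2 p_j) / sqrt(2 p_j (1 - p_j))`,

with allele frequencies `p_j` estimated from the analysis sample and
missing dosages mean-imputed per variant. Relatedness pruning removes, while
any off-diagonal exceeds 0.025, the subject involved in the most offending
pairs (ties broken by lowest subject index) — a deterministic version of
"remove one member of each related pair".

One scale interaction deserves emphasis: off-diagonal GRM entries for truly
unrelated subjects have sampling noise of s.d. `1/sqrt(M)`. The
conventional 0.025 cutoff presumes the million-marker regime
(`1/sqrt(M) ~ 0.001`); at desk-scale `M` of a few thousand the noise
*itself* exceeds the cutoff and pruning at 0.025 would discard most of a
perfectly unrelated cohort. `run_pipeline()` therefore prunes at
`max(0.025, 5/sqrt(M))` by default — the conventional threshold whenever
it is statistically meaningful, a noise-aware one otherwise —
and `prune_related()` keeps 0.025 as its real-data default.

## Population heritability: REML on the rotated model

Per vertex, the phenotype column is residualized on the covariate model
(ordinary least squares; three models are supported — age+sex, +ICV,
+structure volume), then standardized. The variance model is

`y ~ N(0, sigma_g^2 K + sigma_e^2 I)`, `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`.

With the eigendecomposition `K = U diag(lambda) U'` computed **once per
cohort**, the rotated data `U'y` have independent components with variance
`sigma_p^2 (h2 lambda_i + 1 - h2)`. The total variance `sigma_p^2` is
profiled out analytically and `h2` maximized on `[0, 1]` by bounded 1-D
search (tolerance 1e-6). Because fixed effects are projected out before
rotation rather than carried in the likelihood, the criterion is restricted
in the residualized space; the covariate degrees of freedom are ignored in
the rotated likelihood, an approximation that is accurate for small
covariate counts (2–4 here) and documented as such.

Significance uses the likelihood-ratio statistic against `h2 = 0` referred
to the boundary mixture `0.5 chi2_0 + 0.5 chi2_1`; standard errors come
from the numerical curvature of the profile likelihood at the optimum
(undefined, and reported as `NA`, when the optimum sits on a flat
boundary). Estimates are clamped to `[0, 1]` and boundary solutions are
reported, not suppressed. When `K` is numerically an identity (no
relatedness contrast), `h2` is unidentifiable and the fit returns 0 with
`p = 1` and a warning.

Two independent checks accompany the REML path: a **Haseman–Elston
regression** (slope of `y_i y_j` on `K_ij` over all pairs; its raw,
unclamped slope is also reported) and a **permutation test** that recomputes
the LRT on phenotypes permuted against the GRM, with the add-one rule so
`p` never returns exactly zero.

## Twin heritability: ACE maximum likelihood

Twin pairs are modelled as bivariate normal on the standardized scale with
unit variances and pair correlation `a2 + c2` (MZ) or `a2/2 + c2` (DZ).
Opposite-sex pairs are pooled with DZ (coefficient 1/2) with sex as a
covariate; phenotypes are residualized on age and sex, then standardized
jointly across members so the pair covariance scale is preserved (and
`a2 + c2 + e2 = 1` by construction). The likelihood is maximized over
`(s, t) = (a2 + c2, a2 / (a2 + c2))` in the unit box with `L-BFGS-B`,
started from the Falconer estimates (`h2 = 2(r_MZ - r_DZ)`,
`c2 = 2 r_DZ - r_MZ`, on double-entered pair correlations) clamped into the
simplex, plus three seeded random restarts. The no-genetics null (CE model)
is a 1-D optimization over `c2`; the LRT again uses the 0.5/0.5 boundary
mixture. Residualize-then-fit differs from joint fixed-effect ML; with the
small covariate sets used here the difference is negligible and is noted as
a deliberate simplification.

## Reliability and concordance

The ICC is the two-way random-effects, absolute-agreement,
single-measurement form ICC(2,1), computed per vertex from the standard
mean-squares decomposition over subjects × 2 sessions; the literature
rarely states the form, so a one-way ICC(1,1) variant is available via a
flag. Negative estimates are retained; vertices with zero between-subject
variance return `NA` and are excluded from concordance summaries with a
logged count. Concordance between a heritability map and an ICC map is
summarized by Pearson and Spearman correlations plus a scatter-ready paired
table.

## PCA reduction

PCA is computed on the covariance (not correlation) matrix of the centered
measures — measures share units within a structure — returning all
`min(n_subjects - 1, n_vertices)` components in descending eigenvalue
order. Signs are fixed by forcing each component's largest-magnitude
loading positive so runs are comparable. Component scores are then pushed
through the same REML machinery, and the rank agreement between eigenvalue
order and heritability order is a tie-corrected Spearman correlation.

One subtlety discovered during validation: with desk-scale cohorts
(hundreds of subjects), *in-sample* PCA couples component selection to the
realized genetic covariance — the highest-variance sample directions are
systematically enriched, and the lowest-variance directions depleted, in
realized genetic signal, biasing the eigenvalue-vs-heritability rank
correlation upward even when the heritability field is independent of the
variance structure by construction. The independence property is therefore
demonstrated out-of-sample: loadings estimated on one half of the cohort,
component scores and heritability on the other half. At biobank-scale `n`
with anatomically dominated covariance this selection effect is negligible,
which is the regime the property describes.

## Multiple-testing control

Benjamini–Hochberg at `q = 0.05` (through `stats::p.adjust`), pooled by
default across all vertices of the map being tested; a per-structure mode
is available in the report assembly. Pooling across vertices within a
measure is the default because the multiplicity being controlled is the
vertex map, and it is verified against a brute-force threshold search on
short p-lists.

## The synthetic cohort generator

The generator is the study-design mirror of the estimators:

* **Genotypes** — independent biallelic variants, frequencies uniform on
  `[0.05, 0.5]`, hard-call dosages `Binomial(2, p)`; a configurable
  fraction of variants is *flagged* (metadata only) with low imputation
  quality and MAF so the QC filters have something to remove. No linkage
  disequilibrium is simulated.
* **Vertex phenotypes** — `y_v = C beta + W u_v + e_v` with per-variant
  weights of variance `h2_v / M` (infinitesimal architecture: all variants
  causal) and residual variance `1 - h2_v`, so phenotypes have unit
  variance and `h2_v` is exactly the genetic fraction. The heritability
  field over vertices can be a constant, a vector, or Gaussian bumps on the
  vertex lattice ("clusters of high heritability"). Phenotypes are
  standardized by construction; this resolves the open question of
  phenotype scaling in favour of the simplest estimand (`h2 = sigma_g^2`).
* **Twin cohorts** — pair deviates drawn from the ACE covariance directly
  (genetic correlation 1 for MZ, 1/2 for DZ/OS); the default design is 148
  MZ, 120 DZ and 82 opposite-sex pairs (350 pairs), the replication-arm
  design size. Opposite-sex pairs are DZ with discordant sex.
* **Shape cohorts** — the template is a capped tube (an idealized elongated
  structure); each subject's mesh displaces vertex `v` along the template's
  outward radial direction by `0.5 mm` per phenotype unit. Cap apexes lie
  on the medial curve, have no radial direction, and are left in place;
  displacements that would invert the local radius are clamped with a
  warning. Deformation is purely radial — tangential modes are out of
  scope.
* **Rescans** — measurement noise is added at the level of the measure
  matrix: two independent `N(0, sd_v^2)` perturbations of the error-free
  measures per subject, with a per-vertex noise profile. This is equivalent
  to perturbing the meshes radially (radial displacement maps one-to-one
  onto radial distance, as the round-trip test verifies) and keeps the
  implied true ICC, `var_between / (var_between + sd_v^2)`, exact.

What the generator does **not** emulate: MRI acquisition and segmentation
artifacts, spatially correlated vertex noise, LD and rare-variant
architecture, assortative mating, and real anatomical covariance between
vertices. Passing tests therefore show that the estimators recover the
parameters of *this* forward model at the stated sizes, not that real-data
maps are unbiased.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `maf_min`, `rsq_min` | 0.01, 0.5 | — | imputation-era variant QC |
| `hwe_p_min`, `callrate_min` | 1e-6, 0.95 | — | array-QC style |
| pruning threshold | 0.025 | relatedness | treat survivors as unrelated |
| REML tolerance | 1e-6 | h² | bounded 1-D search |
| FDR `q` | 0.05 | — | map localization level |
| ICC form | ICC(2,1) | — | absolute agreement across sessions |
| displacement amplitude | 0.5 | mm / unit | keeps tubes non-self-intersecting |
| rescan noise profile | 0.2–1.2 ramp | measure units | spans poor-to-good reproducibility |

## Validation problem sizes

Chosen once, as the package's own recovery designs: population recovery at
`n = 2000` unrelated subjects × `M = 5000` variants with 50 replicate
phenotypes per heritability level {0, 0.25, 0.5, 0.8}; null calibration
with 1000 null phenotypes; twin recovery at the 148/120/82 design with 100
replicates; designed-property simulations at `n = 800` × `M = 2000`; the
end-to-end demo at `n = 300` × `M = 1000` × 98 vertices. Monte-Carlo
acceptance bands are 3 standard errors of the corresponding design unless a
closed form is exact.

## Known limitations

* GRM-based REML at a few hundred subjects has per-vertex sampling error of
  order `sqrt(2 M) / n`; demo-scale maps are smoke tests, not estimates.
* The medial curve assumes an elongated structure; strongly branched or
  spherical shapes violate its precondition by design.
* The area-based Jacobian measures surface dilation only; it is blind to
  bending without stretch.
* Residualize-then-fit (both cohort types) slightly misstates uncertainty
  relative to joint fixed-effect ML when covariate counts grow.
* The twin model is ACE; dominance (ADE) is out of scope.
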