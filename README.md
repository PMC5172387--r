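# shapeherit

Vertex-wise heritability mapping of subcortical brain shape in R.

The volumes of subcortical structures (hippocampus, caudate, putamen, ...)
are known to be heritable, but a single volume per structure hides where
genetic influences act. `shapeherit` works at the resolution of single
surface vertices on corresponded meshes: it extracts two shape descriptors
per vertex, estimates narrow-sense heritability per vertex in population
and twin designs, relates the resulting maps to measurement reliability,
reduces them by PCA, and localizes significant regions with FDR control. A
fully tested synthetic-cohort generator with known ground truth makes every
stage verifiable without any imaging or genotype download.

## The models

**Shape descriptors.** For each subject mesh (same topology as the
template, so vertex *v* is anatomically matched):

* radial distance: `d_v = min distance from vertex v to the template's
  medial curve` (mm), the curve being fit once on the template;
* log surface Jacobian: `J_v = ln(A_subj(v) / A_tmpl(v))`, with `A(v)` the
  barycentric one-ring area — local surface dilation, `2 ln s` under
  uniform scaling by `s`;
* gross volume by the signed-tetrahedron formula (cm³).

**Population (GRM) heritability.** With the genomic relationship matrix
`K = WW'/M` over standardized dosages, each residualized, standardized
vertex phenotype is modelled as

```
y ~ N(0, sigma_g^2 K + sigma_e^2 I),    h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)
```

fit by restricted maximum likelihood on the spectral rotation of `K`
(one eigendecomposition per cohort, reused across all vertices), with a
Haseman–Elston regression fast path and a permutation check. The test of
`h2 = 0` refers twice the log-likelihood ratio to the boundary mixture
`0.5 chi2_0 + 0.5 chi2_1`.

**Twin (ACE) heritability.** Twin pairs are bivariate normal with pair
correlation `a2 + c2` (MZ) or `a2/2 + c2` (DZ and opposite-sex), maximized
under `a2, c2, e2 >= 0`, `a2 + c2 + e2 = 1`, initialized from Falconer's
`h2 = 2(r_MZ - r_DZ)`; the no-genetics null is tested with the same
mixture-χ² reference.

**Reliability and reduction.** Test–retest ICC(2,1) per vertex from
scan–rescan pairs; full PCA of the vertex measures (descending
eigenvalues, deterministic signs) with REML heritability of component
scores; Benjamini–Hochberg FDR at `q = 0.05` across the map.

## Worked example

Simulate a population cohort of 1,000 unrelated subjects, 2,000 variants
and 40 vertices whose true heritability field has a single bump peaking at
`h2 = 0.6` at vertex 12, then map heritability under the basic (age + sex)
covariate model:

```r
library(shapeherit)

cfg <- sim_config(n_subjects = 1000, n_variants = 2000, n_vertices = 40,
                  h2_field = list(list(center = 12, scale = 4, peak = 0.6)),
                  seed = 42)
g   <- filter_variants(simulate_genotypes(cfg))
k   <- compute_grm(g)
sim <- simulate_vertex_phenotypes(g, cfg)
hm  <- h2_map(sim$phenotypes, k, covariate_model(sim$covariates, "basic"))
hm
#> <heritability_map> 40 vertices, model basic, measure simulated; max h2 = 0.658 at v12
#> # A tibble: 40 x 5
#>   vertex     h2     se       p fdr_sig
#> 1 v1     0.0646 0.0669 0.163   FALSE
#> 2 v2     0.0357 0.0581 0.267   FALSE
#> 3 v3     0.125  0.0650 0.0236  FALSE
#> 4 v5     0.147  0.0656 0.00986 TRUE
#> ...
```

The map's maximum (`0.658 ± 0.07`) lands on the true bump center (vertex
12, true value 0.6); vertices under the bump flanks are FDR-flagged while
the flat background is not. `autoplot(hm)` draws the map with significant
vertices highlighted.

A twin cohort at the replication design size (148 MZ + 120 DZ + 82
opposite-sex pairs) with `a2 = 0.6`, `c2 = 0.2`:

```r
tw  <- simulate_twin_cohort(sim_config(h2_field = 0.6, c2 = 0.2, seed = 7))
fit <- ace_ml(tw$cohort)
tidy(fit)
#>   term  estimate
#> 1 a2     0.757
#> 2 c2     0.00637
#> 3 e2     0.236
glance(fit)
#>   logLik logLik.null   LRT  p.value n.pairs
#> 1  -911.       -930.  38.6 2.64e-10     350
```

At 350 pairs a single replicate is noisy (here `a2` overshoots to 0.76 and
the shared-environment share is absorbed); across 100 replicates the mean
estimate is within 0.01 of the truth (see the acceptance checks). The
end-to-end driver `run_pipeline(analysis_config(...))` chains simulation,
QC, GRM, shape measurement, all covariate models, ICC, PCA and the FDR
report into one reproducible run.

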