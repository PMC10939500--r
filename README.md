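# craniomorph

Quantitative genotype-to-shape analysis for cohorts of 3D bone surfaces.

Sparse anatomical landmarks cannot resolve the subtle, localized shape
changes produced by normal-range genetic variation — a slightly deeper
mandibular ramus, a wider gap between palatine plates. `craniomorph`
implements the dense-correspondence alternative used in quantitative
craniofacial genetics: a template surface is non-rigidly registered onto
every specimen so that each bone becomes a `V x 3` configuration of
corresponding pseudo-landmarks, and genotype effects are then estimated and
permutation-tested on the whole structure and at every vertex.

The pipeline:

1. **Registration** — similarity alignment from named fiducial landmarks
   (orthogonal Procrustes), then smoothed iterative-closest-point non-rigid
   registration with an annealed Gaussian bandwidth over template geodesics;
2. **Generalized Procrustes analysis** — remove position, scale (unit
   centroid size), and orientation (proper rotations only);
3. **PCA reduction** — retain the principal components explaining 96% of the
   variance (configurable), normalize scores to unit variance;
4. **Partial effect of genotype** — sex and litter enter as k−1 dummy-coded
   nuisance covariates; double residualization (Frisch–Waugh) gives

   `partial R² = (SSE_reduced − SSE_full) / SSE_reduced`,

   the nuisance-adjusted variance explained by the genotype contrast (with a
   single contrast, the PLS step reduces to least squares);
5. **Freedman–Lane permutation test** — permute the residualized contrast,
   re-residualize, recompute; `p = (1 + #{R²_perm ≥ R²_obs}) / (1 + B)`,
   default B = 10,000;
6. **Effect maps** — per-vertex partial R² by reversing the PC projection,
   and the genotype coefficient field projected on outward vertex normals
   (positive = protrusion/red, negative = depression/blue), written as CSV +
   colored ASCII PLY.

A first-class synthetic-cohort generator (`generate_cohort`) reproduces the
statistical structure the analysis assumes — localized genotype bump along
outward normals, smooth per-litter random fields, a sex field, iid vertex
noise, arbitrary similarity transforms, and optional de-correspondence
(remesh + vertex shuffle) — with full ground truth, so every stage is
validated by parameter recovery. Side modules compute single-SNP F_ST
(Hudson and Wright forms) and Poisson-statistics ddPCR quantification of
allele-specific expression with delta-method confidence intervals.

## Worked example

```r
library(craniomorph)

template <- make_template(12)                       # closed bone-like surface
patch    <- vertex_patch(template, 40, rings = 2)   # connected effect region

spec <- cohort_spec(n_per_group = c(20, 24),        # 20 WT + 24 variant
                    genotype_effect_amplitude = 0.3,
                    effect_patch = patch,
                    sex_effect_amplitude = 0.02,
                    litter_count = 7, litter_sd = 0.01,
                    noise_sd = 0.02, seed = 11)
cohort  <- generate_cohort(template, spec)
aligned <- gpa(as_corresponded(cohort))
effect  <- fit_genotype_effect(aligned, genotype_levels = c("WT", "VAR"),
                               n_permutations = 10000, seed = 11)
aligned
#> <cm_aligned> 44 shapes x 266 vertices (GPA, 4 iterations)
effect
#> <cm_effect> global partial R2 = 0.0301, p = 0.0008999 (10000 permutations, 40 PCs retained)

which.max(effect$per_vertex_R2)                     # localizes to the patch
#> [1] 40
effect$normal_displacement[40]                      # outward displacement
#> [1] 0.0239
```

The global partial R² (0.030) looks small because the 40 retained PCs are
normalized to unit variance, so a localized single-mode effect can explain at
most ~1/40 of the normalized variance; the permutation test is calibrated for
exactly this statistic, and here rejects decisively (p ≈ 9e-4). The top
per-vertex R² lands on the seed vertex of the injected patch, and its normal
displacement is positive — an outward bump, as simulated.

The molecular calculators are one-liners:

```r
hudson_fst(0.52, 0.02)                 # EUR vs EAS allele frequencies
#> [1] 0.48151
allelic_fraction(droplet_counts(20000, 5200, 9800))
#> FAM fraction 0.3090 [0.3018, 0.3162]  (lambda FAM 0.3011, HEX 0.6733)
```

For file-based cohorts, `read_manifest()` + `build_cohort()` register OBJ
meshes from a manifest CSV, and `run_pipeline()` orchestrates the whole
analysis from a single config (R list, JSON, or YAML), writing a report JSON
and colored effect maps.

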