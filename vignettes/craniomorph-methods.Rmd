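---
title: "Methods: dense-correspondence shape analysis and genotype effect testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dense-correspondence shape analysis and genotype effect testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniomorph)
```

## The problem

Subtle, normal-range genetic effects on craniofacial bone shape are invisible
to sparse landmarking: a handful of anatomical points cannot resolve a
localized depression in a mandibular ramus or a widening between palatine
plates. The standard remedy in quantitative craniofacial genetics is *dense
correspondence*: a template surface is registered onto every specimen so that
vertex *i* means the same anatomical location in every animal, turning each
bone into a `V x 3` configuration of pseudo-landmarks. Genotype effects can
then be estimated and tested at the level of the whole structure and at every
single vertex.

`craniomorph` implements this pipeline end to end for cohorts of triangulated
bone surfaces (Wavefront OBJ) with a two-level genotype contrast (e.g.
wild-type vs heterozygote) and categorical nuisance covariates (sex, litter),
together with a synthetic-cohort generator that reproduces the statistical
structure the analysis assumes — so every stage can be validated against
known ground truth. Two small, self-contained molecular calculators round out
the package: a single-SNP fixation index (F_ST) and Poisson quantification of
droplet-digital PCR (ddPCR) counts for allele-specific expression.

## Pipeline model, stage by stage

### Dense correspondence (registration)

Registration is two-phase. A similarity transform (proper rotation,
translation, isotropic scale) is first fitted by least squares to named
fiducial landmarks shared between template and specimen (the Umeyama
closed-form solution; reflections are excluded because bones are chiral).
The non-rigid phase is a smoothed iterative-closest-point scheme: each
template vertex finds its nearest point on the target surface
(point-to-triangle, so remeshed targets with no shared vertices are fine),
the raw displacement field is smoothed by a Gaussian kernel over edge-graph
shortest-path distances on the template (a geodesic approximation), and a
fraction `step` of the smoothed field is applied. The bandwidth anneals
geometrically from `sigma_init` (default 8 mean-edge-lengths — near-rigid
updates) to `sigma_final` (default 0.8 — local detail), over `iterations`
(default 30) steps. The procedure is deterministic given its inputs; a
residual trace is returned and a non-decreasing tail flags non-convergence
rather than aborting.

Assumptions worth stating: targets are complete, hole-free surfaces roughly
similar to the template (no partial scans), and the template-to-target
direction only is used — there is no symmetric term. The defaults were tuned
on synthetic cohorts only; real micro-CT surfaces may need a longer schedule.

### Generalized Procrustes analysis

Position, scale, and orientation are nuisance for shape. Each configuration
is centered, scaled to unit centroid size (the square root of summed squared
vertex distances to the centroid), and rotated to the evolving mean shape by
the SVD solution restricted to proper rotations; the mean is renormalized to
unit size each round. Iteration stops when the root-mean-square change of the
mean falls below `tol` (default 1e-10) or after `max_iter` (default 100)
rounds. Aligned shapes are *not* projected to the tangent space before PCA:
shape variation at the scales simulated and studied here is small (Procrustes
distances well below 0.1), where the linear approximation is safe. That is a
deliberate simplification and is the main caveat when the pipeline is applied
to cohorts with large shape variance.

### PCA reduction and the partial effect of genotype

Flattened aligned shapes are reduced by PCA; the smallest number of leading
components whose cumulative variance fraction reaches the retention threshold
(default 0.96) is kept, after discarding numerically null axes. Retained
scores are normalized to unit variance per component, which puts every
retained mode on an equal footing in the global test — a deliberate property
of the method with consequences discussed under *Power* below.

The covariate design codes each k-level categorical nuisance factor as k-1
binary dummies plus an intercept, and genotype as a single 0/1 contrast
(reference vs variant), matching pairwise group comparisons rather than an
additive allele-dosage code. The partial effect is computed by double
residualization (Frisch–Waugh): both the normalized scores `Y` and the
genotype contrast `g` are residualized on the nuisance block, and the
residual scores are regressed on the residual contrast. With a single
predictor the partial-least-squares step coincides with ordinary least
squares, and the partial effect size is

```
partial R2 = ||fitted||^2 / ||Y_residual||^2
           = (SSE_reduced - SSE_full) / SSE_reduced,
```

the fraction of nuisance-adjusted variance explained by genotype. The test
suite verifies the identity of the two forms against an independent
normal-equations oracle to 1e-10 on random designs.

### Freedman–Lane permutation test

Significance comes from a Freedman–Lane permutation scheme: the residualized
genotype vector is permuted and the *entire* partial-R2 computation is
repeated for each permutation — including re-residualization of the permuted
vector on the nuisance design. The re-residualization step matters: a
permuted residual vector generally leaves the nuisance-orthogonal subspace,
where the response residuals have no mass, so skipping it deflates every
permuted statistic and inflates the false-positive rate drastically (we
measured ~90% rejection at alpha = 0.05 on null cohorts without it, versus
the nominal ~5% with it). The p-value uses the add-one correction,

```
p = (1 + #{R2_perm >= R2_obs}) / (1 + B),
```

so `p >= 1/(B+1)` always and ties count against rejection. The default `B` is
10,000; the simulation studies in the test suite use 200–500 permutations,
which bounds their attainable p-values at 1/201–1/501 and is ample for
calibration and power checks at alpha = 0.05.

### Per-vertex effects and normal-displacement maps

The PC projection is then reversed: nuisance-only and full-model residuals
are de-normalized (multiplied back by the score standard deviations, so
fields are in aligned-shape units rather than normalized-score units) and
back-projected through the retained components. Per vertex, the three
coordinates are pooled:

```
R2[v] = (SSE_reduced[v] - SSE_full[v]) / SSE_reduced[v],
```

one value per vertex, matching one-color-per-vertex effect maps. The genotype
coefficient vector is back-projected the same way into a `V x 3` field — the
shape change per unit genotype contrast — and summarized as its signed
projection on the outward unit vertex normals of the mean shape
(area-weighted incident-face average): positive = outward (protrusion, red),
negative = inward (depression, blue). No multiple-testing correction is
applied across vertices; the per-vertex output is an effect-size map, and the
global permutation test carries the inferential burden. Under the null the
per-vertex R2 centers near `1/(N - q - 1)` for `q` nuisance columns, a handy
reading aid for the maps (verified by simulation in the tests).

## The synthetic-cohort generator

`generate_cohort()` draws specimens as

```
shape_i = template
        + g_i * amplitude * taper(patch) * outward normals     (genotype)
        + s_i * sex_field                                      (sex)
        + litter_field[litter_i]                               (litter)
        + iid Gaussian vertex noise                            (noise_sd)
   then: optional random similarity transform, optional de-correspondence
```

- the genotype bump is supported *exactly* on a connected vertex patch, with
  a breadth-first-depth taper so it fades smoothly to the patch boundary;
- the sex field is a fixed smooth (half-sine in the long axis) normal
  displacement;
- litter fields are smooth random fields — Gaussian coefficients on a coarse
  radial-basis expansion of the template, row-normalized so the per-vertex
  standard deviation is `litter_sd` — because litter is a structured,
  spatially coherent confounder, not iid noise;
- de-correspondence applies midpoint (1-to-4) triangle subdivision to the
  deformed specimen followed by random vertex and face reordering. This
  changes the vertex count and destroys index correspondence, giving the
  registration stage a genuine task, while the original template vertices
  survive as an exact, known subset — the ground-truth correspondence used by
  the recovery tests. It is a mild stand-in for full isotropic remeshing: the
  target's vertex *density* changes but its vertex *positions* still contain
  the originals.

All randomness flows from one master seed through named substreams
(`substream_seed`), so cohort geometry, noise, transforms, and permutation
draws can be reproduced independently.

### Default study conditions

Simulation studies in the tests and the acceptance script use one fixed set
of conditions, chosen to mirror the motivating study design: 20 reference +
24 variant specimens spanning 7 litters and 2 sexes; template resolution 16
(V = 482 vertices, a desk-scale stand-in for dense bone meshes); vertex noise
`noise_sd = 0.02` (about 1% of the ~2-unit template length); litter field sd
0.01 and sex amplitude 0.02 (structured confounders at half the noise scale);
genotype bump on a 2-ring, 17-vertex patch.

### Power and the amplitude ladder

Two properties of the method set its detection limit, and both are worth
knowing before reading any recovery result:

1. **PC dilution.** Normalizing every retained PC to unit variance means a
   perfectly captured single-mode effect can explain at most ~1/m of the
   normalized variance (m ≈ 40 retained components at these conditions). The
   observed global R2 therefore saturates near 0.05 while the null
   distribution centers at `1/(N-q-1)` ≈ 0.029 — the test works on a narrow
   but sufficient margin.
2. **Eigenvalue threshold.** PCA only isolates the effect mode once its
   eigenvalue exceeds the noise bulk edge, `sigma^2 (1 + sqrt(3V/N))^2`
   (Marchenko–Pastur). At V = 482, N = 44, `noise_sd = 0.02` this happens
   near bump amplitude ~0.12; below it the effect leaks across many
   components and global power decays.

The recovery study's amplitude ladder (0.05, 0.15, 0.40) was therefore placed
below, at, and well above this threshold. The acceptance suite recomputes the
ladder at every run (40 replicates per level): global power at alpha = 0.05
climbs steeply through the threshold — about 0.2 at the lowest level, near
0.9 at the middle, 1.0 at the top — and at the top level the maximal
per-vertex R2 falls inside the one-ring-dilated true patch in every
replicate. Because the amplitudes are free
parameters of the synthetic design, the recovery study is self-referential by
construction: it validates the estimator's internal consistency, not any
field-realistic effect size.

### What the generator does **not** emulate

Real micro-CT cohorts bring segmentation artifacts, partial or damaged
surfaces, bilateral asymmetry, allometric size–shape covariance, non-Gaussian
and spatially correlated digitization error, and litter effects that interact
with genotype. None of these are simulated, so green tests demonstrate
correctness of the algorithms under their stated model — not robustness of
the pipeline to everything real data can do.

## Molecular calculators

**F_ST.** The default estimator is the two-population Hudson form,
`(p1 - p2)^2 / (p1(1-p2) + p2(1-p1))`, without finite-sample correction —
with reference-panel-scale samples the correction terms are order 1/n and
negligible. A Wright-style variance-partition form `(H_T - H_S)/H_T` is
provided as an alternative; the two do not coincide away from the boundaries
(0.48 vs 0.32 at frequencies 0.52/0.02), which is exactly why the estimator
choice is surfaced as an explicit argument. Both are symmetric, zero at equal
frequencies, one at opposite fixation, and undefined (a classed error) when
both populations are fixed for the same allele.

**ddPCR.** Per-channel template concentration uses Poisson occupancy,
`lambda = -log(1 - positives/droplets)`, with a saturation error when every
droplet is positive. The allelic fraction is `lambda_F / (lambda_F +
lambda_H)`; its 95% interval comes from first-order (delta-method)
propagation of the binomial variance of each positive proportion — chosen
over a bootstrap because it is closed-form and directly testable: simulated
coverage at 20,000 droplets and fraction 0.3 lands at 0.93–0.97 across seed
batches, within the nominal band. Expression change against a genomic-DNA
balance control is reported as signed percent change of the FAM:HEX
concentration ratio relative to the control ratio, so negative values mean
the tracked allele is down (a halving reads -50). Double-positive droplets
count in both channels, per the duplex assay model.

## Numerical choices and degenerate inputs

- Vertex indices are 1-based everywhere inside the package (the R
  convention); conversion happens only at the OBJ/PLY boundary.
- Rotations are always proper (det +1); the SVD sign correction applies at
  every Procrustes fit.
- PCA drops components with variance below 1e-12 of the leading one before
  the retention rule; score normalization refuses zero-variance columns.
- Rank-deficient nuisance designs and genotype contrasts inside the nuisance
  span raise classed `collinear_design` errors rather than producing NaN.
- Degenerate meshes (coincident vertices, zero vertex stars), collinear
  landmark triples, saturated ddPCR channels, and same-allele-fixed F_ST all
  raise classed errors named in the function documentation.
- All-zero effect fields, empty cohorts, and zero-size shapes are rejected at
  construction, not deep in the computation.

## Known limitations

- No tangent-space projection before PCA (see above); no semilandmark
  sliding, bilateral symmetrization, or allometry regression.
- Litter is a fixed dummy-coded nuisance, not a random effect; with many
  small litters this costs degrees of freedom.
- The registration has no protection against topological mismatch (holes,
  disconnected fragments) and no bidirectional consistency term.
- The per-vertex maps are descriptive; the optional family-wise max-R2
  permutation correction is not implemented in this version.
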