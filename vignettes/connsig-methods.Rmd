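---
title: "Methods: from connectomes to gene cascades"
author: "connsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from connectomes to gene cascades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connsig)
```

`connsig` chains four statistical procedures: functional-connectivity
feature extraction, penalized classification with weight back-projection,
spatially constrained gene-map similarity testing, and path-analysis
structural modelling of gene cascades. This vignette documents each model,
its assumptions, the tunable parameters, the numerical choices, and what
the synthetic-data generator does and does not emulate.

## 1. Connectivity features

**Dual regression.** Given a subject 4-D volume and a shared basis of K
spatial component maps, stage 1 regresses every timepoint's masked image on
the K maps (ordinary least squares), yielding a T × K matrix of subject
time courses; stage 2 regresses every voxel's time series on the
variance-normalized time courses, yielding subject-specific maps. The
variance normalization between stages is the common dual-regression
convention; it leaves the downstream Pearson FC unchanged, because
correlation is invariant to affine rescaling of either series. Rank
deficiency of the basis within the mask is refused with the design's
condition number (threshold 1e8), and constant inputs are flagged
degenerate rather than silently producing zero divisions.

**FC features.** Functional connectivity is the Pearson correlation of each
retained component pair over timepoints, assembled as the upper triangle in
lexicographic (i, j), i < j order over the sorted inclusion list. The
inclusion list is how manual artifact-component exclusions enter the
pipeline; it is a configuration input, not something the package infers.
Raw correlations are used; no Fisher z transform is applied before
classification (exposing one would be trivial, but the default pipeline
deliberately classifies on the correlation scale).

## 2. Signature model

**Classifier.** Penalized logistic regression with the elastic-net penalty,
parameterized by inverse regularization strength C and L1 ratio. The
coordinate-descent solver (`glmnet`) is invoked with
`lambda = 1 / (n_train · C)` and `alpha = l1_ratio`, which makes the grids
directly comparable across training-set sizes. Defaults: C log-spaced over
[1e-2, 1e2] (25 points) and l1_ratio ∈ {0.05, …, 1.0}; features are
z-scored inside the solver (customary for elastic net; recorded in the
configuration), and class weighting, when enabled, uses the
n/(2·n_class) convention.

**Cross-validation.** Stratified k-fold with k = 7 by default, chosen so
held-out folds contain a few subjects at typical cohort sizes (tens per
group). The (C, l1_ratio) grid point maximizing mean held-out accuracy is
selected, with ties broken toward sparser models (larger l1_ratio, then
smaller C). Per-fold models refit at the chosen point provide the weights;
metrics (accuracy, balanced accuracy, ROC-AUC, PR-AUC) are reported as mean
[SD] across folds. Fold assignment is seeded, and a split that would leave
a single-class training set is redrawn with a logged message. Note that
reporting held-out metrics at the tuned grid point carries the usual
max-over-grid optimism; the package's own permutation control therefore
permutes labels at *fixed* hyperparameters, which is the correct chance
baseline for this design.

**Back-projection.** Edge weights are averaged across folds; component i
receives w_i = Σ_j W̄(i, j); the voxel signature is Σ_i w_i · IC_i. Both
steps are linear, so signatures superpose, a property the tests exploit.
Stability is quantified as pairwise cross-fold Pearson correlations of the
edge-weight vectors, the IC-weight vectors, and the voxel maps; an all-zero
fold yields undefined (NA) pairs rather than being dropped.

## 3. Gene-map similarity under spatial-autocorrelation-preserving nulls

**Statistic.** Spearman's ρ between the signature and a gene map across
voxels in scope (whole cortex or one parcellation region), using average
ranks for ties. Monotone invariance makes the score insensitive to the
arbitrary scaling of expression maps.

**Why a constrained null.** Brain maps are spatially smooth; under a naive
permutation null the apparent degrees of freedom equal the voxel count, and
smooth-versus-smooth correlations look wildly significant. The calibration
test in `test-acceptance.R` measures this directly: at a ~9,600-voxel mask
the naive null rejects ~85% of truly unrelated smoothed gene maps at
α = 0.05, while the variogram-matched surrogate null stays in [0.03, 0.07].

**Surrogates.** For each surrogate: permute the source values over the
mask; smooth with a k-nearest-neighbour inverse-distance kernel at each
candidate neighbourhood size k ∈ {3, 10, 30, 80, 150, 300, 600}; fit scale
α and nugget β (nonnegative least squares of the source variogram on the
smoothed map's variogram plus a constant); form
√α·smoothed + √β·white noise; rank-remap onto the source's empirical value
distribution; and keep the candidate k whose *realized* surrogate variogram
has minimal SSE against the source. Two choices deserve comment:

* The candidate set extends to k = 600 because, at 2 mm voxels, a
  120-neighbour kernel (~6 mm radius) cannot reproduce fields with
  correlation lengths of 10 mm or more; with the wider set the mean
  surrogate variogram sits within a few percent relative SSE of the source.
* Scale selection scores the final, rank-remapped surrogate rather than the
  analytic mixture, because remapping itself perturbs the variogram;
  selecting on the pre-remap approximation left surrogate nulls ~10%
  over-dispersed (a conservative test with reduced power).

**Variogram.** γ(h) = mean of ½(x_i − x_j)² over voxel pairs binned by
mm distance: 25 bins, pairs up to the 50th percentile of pairwise
distances, estimated on a seeded 500-voxel subsample for tractability.
Empty bins are dropped with a warning.

**Inference.** With n surrogates (default 1000; at least ~100 for stable
moments), z = (ρ_obs − mean ρ_null)/sd ρ_null and a two-sided normal tail
give the p-value. Families for Benjamini–Hochberg and Bonferroni
adjustment are all genes at one scope: the whole-cortex family for
cortical results, and the within-region family for regional results.
Cortical and subcortical maps are scaled differently by construction and
are never pooled into one whole-brain comparison. Regional scores reuse the
cortical surrogate ensemble restricted to each region's voxels, so the
regional null respects both the signature's autocorrelation and the
region's geometry; region-level p-values are also what the cascade
retention filter consumes, since the cascade model is fitted to
region-level scores.

## 4. Path-analysis SEM

**Model.** Observed variables only; directed acyclic edges carry linear
coefficients; endogenous residuals and exogenous variances are free;
exogenous covariances are fixed at zero unless declared (`cov: a ~~ b` in
model files), so diagram variants can be encoded either way. Estimation
minimizes the Wishart ML discrepancy
F_ML = ln|Σ(θ)| − ln|S| + tr(S·Σ(θ)⁻¹) − p with χ² = (N−1)·F_ML. The
model is fitted to the covariance matrix of the similarity scores (not the
correlation matrix); coefficient z statistics are invariant to common
rescaling, which the tests check.

**Numerics.** Variances are log-parameterized to stay positive; the
implied covariance is built as (I−B)⁻¹Ψ(I−B)⁻ᵀ and any non-PD iterate
receives a large finite penalty so BFGS can retreat. Starting values are
the equation-wise OLS solutions computed from S, which for recursive
models with unconstrained exogenous covariances are already the ML
estimates; three seeded random restarts are tried on non-convergence, and
persistent failure is an error with diagnostics, never a truncated result.
Standard errors come from the inverse expected information,
vcov = 2/(N−1) · H⁻¹ with H the numerical Hessian of F_ML at the optimum
(delta method back-transforms the variance parameters). The 200-replicate
recovery test keeps the information-based SE within 15% of the empirical
spread and 95% CI coverage inside [0.92, 0.98].

**Fit indices.** CFI = 1 − max(χ²_M − df_M, 0)/max(χ²_B − df_B,
χ²_M − df_M, 0); TLI_raw = ((χ²_B/df_B) − (χ²_M/df_M))/((χ²_B/df_B) − 1)
with the reported TLI truncated at 1 (the raw value is retained); RMSEA =
√(max(χ²_M − df_M, 0)/(df_M·(N−1))). The independence baseline has the
closed form χ²_B = −(N−1)·ln det R, which doubles as an oracle in the test
suite. When χ² ≤ df, CFI = TLI = 1 and RMSEA = 0 exactly — the "exact fit"
limit that fitting any cascade to its own model-implied population
covariance reproduces analytically, and the configuration
`scripts/acceptance.R` recomputes. With df = 0 (saturated models) TLI and
RMSEA are undefined and reported as NA.

**Model search.** Variants are generated by single-edge reversal and/or by
permuting the assignment of variables to positions in the cascade graph;
cyclic variants are discarded and counted, duplicates removed by canonical
edge-set signature, and fits ranked by RMSEA ascending then CFI
descending. Strict flags use CFI > 0.95, TLI > 0.95, RMSEA < 0.05; the
secondary lenient band uses the conventional CFI > 0.90, TLI > 0.90,
RMSEA < 0.08. Covariance-equivalent variants (e.g., reversing the root
edge of a chain) tie at the base model's discrepancy; the ranking reports
ties rather than pretending a unique winner.

**Retention filter.** Region × gene scores enter the SEM table only when
their regional permutation p-value is below 0.5 — a deliberately lenient
filter that discards clearly unrelated scores while keeping enough regions
to fit; regions missing any retained gene are dropped listwise and the
counts logged. Assembly refuses tables with fewer than variables + 1 rows.

**Cascade templates.** `inst/models/` ships two editable plain-text
hypothesized cascades (a cortisol-driven neurotoxicity chain over
HSD11B1/NR3C1/H6PD/GNAI2/GRIN2A/GRIN2B, and a ROS→JNK→p53 apoptosis
cascade over SOD2/MAPK8/TP53/PMAIP1/BCL2L1/BAX/CYCS). The exact node and
edge sets of such diagrams are scientific hypotheses; the files are
templates to edit, not package truth.

## 5. What the synthetic-data generator does and does not emulate

The generator exists so every stage has inputs with known ground truth:

* **IC bases** are Gaussian-smoothed white noise (correlation length =
  kernel FWHM in mm) under a Gaussian localization envelope — smooth and
  roughly localized like real group ICs, but not constrained to
  plausible network topographies.
* **Cohorts** draw each subject's T × K time series i.i.d. from a group
  covariance plus white noise. Group differences are planted by overwriting
  chosen correlation entries and projecting to the nearest positive-definite
  matrix (eigenvalue clipping at 1e-6), so the generator is always valid.
  Defaults emulate the target study conditions: three groups of 30/19/22
  subjects and 400 timepoints (a 10-minute scan sampled every 1.5 s). The
  base correlation (0.1–0.2) and noise SD (0.5) are conventions — no
  published estimate of real IC time-course covariance structure backs
  them — and there is no hemodynamic forward model, no temporal
  autocorrelation, and no motion or physiological noise.
* **Gene maps** are smoothed Gaussian fields; a target correlation ρ is
  planted by mixing ρ·standardized(target) + √(1−ρ²)·independent field.
  Real expression maps have anatomical structure, inter-gene correlation,
  and donor-specific noise that this does not reproduce.
* **Parcellations** are Voronoi partitions of the mask — contiguous,
  exhaustive, disjoint, but not anatomically shaped.
* **Path data** are generated in topological order as coefficient-weighted
  parent sums plus Gaussian residuals; the exact model-implied covariance
  is available in closed form for exact-fit tests.

Passing tests on these inputs demonstrates that the *inference machinery*
is correct and calibrated under its stated assumptions; it does not
demonstrate that any particular clinical dataset satisfies those
assumptions.

## 6. Problem sizes and seeds used by the test suite

Unit tests run on ~10³-voxel masks in seconds. The behavioural checks use
the sizes the corresponding guarantees are stated for: surrogate
calibration and power on a ~9,600-voxel spherical mask (32³ grid, 2 mm
voxels) with 200 surrogates, 500 independent and 150 planted (ρ = 0.3)
gene maps of 10 mm correlation length; classifier recovery at 60 subjects
per group, T = 400, five planted edges (Δr = 0.4) among 120, averaged over
20 seeds with a reduced 7 × 3 tuning grid; SEM recovery over 200
replicates at n = 500. All randomness flows through explicit integer
seeds; every generator is a pure function of its arguments, and per-stage
seeds in the pipeline derive from one master seed by stable hashing, so
any stage can be reproduced in isolation.

## 7. Known limitations

* The surrogate model (permute–smooth–remap) cannot produce variograms
  above the field's sill, so maps with strong long-range *negative*
  structure are matched only approximately; the realized-SSE selection
  keeps the induced miscalibration within the tested band.
* The z-approximated permutation p-value assumes an approximately normal
  null; with very few surrogates or tiny scopes the empirical tail may
  disagree. The minimum scope size (10 voxels) and the n ≥ 100 surrogate
  recommendation are guardrails, not proofs.
* The SEM is fully observed (no latent variables, no mean structure, no
  robust/WLS estimators) and similarity scores enter it as if they were
  i.i.d. observations across regions, ignoring spatial dependence between
  neighbouring regions.
* ROC-AUC and PR-AUC are undefined on single-class held-out folds and are
  reported as NA for those folds; accuracy summaries ignore NAs.
* Choosing hyperparameters and reporting metrics on the same folds is the
  design being modelled, and its optimism is documented rather than
  removed; an outer validation loop is the obvious extension.
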