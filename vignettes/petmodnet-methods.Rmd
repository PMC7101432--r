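---
title: "Methods: PET radiomics module networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PET radiomics module networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petmodnet)
```

`petmodnet` links quantitative ¹⁸F-FDG PET image features to tumor
transcriptomics in a four-stage pipeline: tumor delineation and a
28-feature radiomics battery; a paired tumor-vs-normal differential
expression filter; a module-network learner that explains gene-module
expression with threshold trees over the radiomic features; and a
pathway-level functional roll-up. This vignette is the package's own
account of each model, its assumptions, the tunable parameters, and the
numerical and design choices behind them.

## Imaging and segmentation

PET volumes carry activity concentration in Bq/ml; `compute_suv()`
rescales by body weight (g) over injected dose (Bq), assuming decay
correction upstream. Voxel spacing is in mm; search boxes are 0-based
and half-open; grid connectivity is the 26-neighborhood throughout, and
argmax ties break at the lowest linear (row-major) index.

Two delineation strategies are implemented:

* `segment_fixed_fraction()` keeps the 26-connected component, around
  the hottest voxel, of voxels at or above `fraction × SUVmax` (default
  0.41). This is the widely used fixed-threshold baseline.
* `segment_fuzzy_adaptive()` fits a 1-D Gaussian mixture (2 or 3
  classes) to the box SUVs by EM and keeps the largest connected
  component of voxels whose posterior membership in the hottest class
  exceeds 0.5. It stands in for locally adaptive Bayesian delineation
  methods, which we deliberately do not reproduce: downstream analysis
  needs a defensible mask, not a specific algorithm, and the provenance
  tag (`fuzzy_adaptive`) records the substitution. EM initializes class
  means evenly across the data range (quantile initialization collapses
  when background dominates the box), floors class variances at
  `1e-3 × sd` so noiseless plateaus cannot degenerate, and restarts
  with seeded jitter (at most 5 times) if a class empties.

On blurred phantoms the posterior rule includes much of the
partial-volume rim, so fuzzy volumes systematically exceed fixed-41%
volumes — the direction expected for irregular heterogeneous tumors —
while on noiseless unblurred objects both recover the truth exactly.
`compare_matv()` compares paired volume lists with a two-sided Wilcoxon
signed-rank test (exact for n ≤ 15 without ties); the test choice is
ours, as volume differences are skewed.

## The radiomics battery

`extract_features()` emits exactly 28 named features: 5 intensity, 7
shape, 7 co-occurrence, 9 size-zone. Choices that matter:

* **Discretization.** Fixed bin number (default 64) between ROI min and
  max: `bin(x) = floor(n_bins (x − min)/(max − min)) + 1`, with the
  maximum mapped to the top bin; a constant ROI maps to bin 1 and is
  flagged degenerate. FBN makes texture invariant to affine intensity
  rescaling — and, as a flip side, *range-relative*: a homogeneous
  noisy tumor spreads its tiny range across all 64 bins and can show
  higher normalized contrast (inertia) than a lumpy one. Tests of
  heterogeneity therefore also examine the de-normalized contrast
  (inertia × bin width²) and SUV_COV.
* **Co-occurrence.** One global matrix merged over the 13 unique
  directions of the 26-neighborhood, symmetrized and normalized.
  Adjacency is in grid steps; spacing anisotropy is intentionally
  ignored for texture (no resampling — features are computed on the
  native grid). A single-voxel mask has no pairs; the stated convention
  is ASM = 1 and all other co-occurrence features 0; correlation is 0
  whenever the marginal variance vanishes.
* **Size zones.** 26-connected components of equal-bin voxels; the
  feature set (zone percentage, small/large area emphasis, intensity
  and size-zone variability, high/low intensity (large area) emphases)
  follows the standard definitions, verified against brute-force
  enumeration.
* **Shape.** Volume is voxel count × voxel volume (MATV in ml).
  Surface area uses a *coarea* estimator: the binary mask is
  anti-aliased with a Gaussian of 0.6 voxel and the gradient magnitude
  is integrated, which equals the iso-surface area averaged over
  levels. Measuring the raw voxel boundary overestimates curved
  surfaces by 25–50%; the coarea estimate is within about 1% for
  digitized spheres of radius ≥ 8 voxels and — unlike fixed-diagonal
  mesh extractors — is exactly invariant under 90° grid rotations,
  which the whole battery is tested to be. A voxel-face mode
  (`surface = "voxel_faces"`) remains for sensitivity checks and is
  exact for axis-aligned boxes, which is how the closed-form cube
  check is performed. Two features lack a universal definition and are
  defined explicitly here: `irregularity = 1 − sphericity` and
  `max_distance_to_background` = the largest Euclidean distance (mm,
  spacing-aware) from a tumor voxel to the nearest background voxel.
  SUV_COV uses the population (not sample) standard deviation.

`normalize_cohort_features()` rescales each feature to [0, 1] across
the cohort (dropping cohort-constant features with a warning), so
learned thresholds read directly as percentages of the cohort range.

## Paired differential expression

The stage order is fixed: normexp background correction → log2 →
quantile between-array normalization → replicate-probe averaging →
paired moderated t → BH adjustment → selection. Parameter fitting for
normexp uses `limma::normexp.fit(method = "mle")` per array
(independent arrays); the corrected value is the closed-form posterior
mean `E[S | X = x]` of the exponential-signal/Gaussian-noise
convolution, computed with a log-space Mills ratio so it stays positive
and monotone far below the background mean. Quantile normalization and
replicate averaging delegate to `limma::normalizeQuantiles(ties =
TRUE)` and `limma::avereps`.

The paired statistic shrinks per-probe variances with the standard
empirical-Bayes moment-matching estimator (`limma::fitFDist` on the
sample variances of the paired differences): `s̃² = (d0 s0² + (n−1) s²)
/ (d0 + n − 1)`, with `t̃ = mean(d)/(s̃/√n)` on `n − 1 + d0` degrees of
freedom, capped at the pooled residual df. `prior_df` can be forced to
0 (ordinary paired t) or `Inf` (full shrinkage) for verification; the
default estimate reproduces the `limma::lmFit`/`eBayes` route to
numerical precision. Fold-change is defined as the mean per-patient
paired log2 difference, so the selection rule `p_BH < 0.01` and
`|log2FC| > 1` (both strict) matches "FDR 1% and fold-change > 2".

One property worth knowing: quantile normalization maps each array's
extreme ranks onto the cross-array mean, which can crush the
fold-change of a truly regulated probe that tops the intensity ranking.
On planted fixtures this costs at most the single top-ranked probe.

## The module network

The learner groups retained probes into modules whose expression is
explained by **regulator trees** over the normalized features. The
expression handed to it is the per-probe-centered paired log2
tumor/normal difference — the log-ratio convention of module-network
tools; centering removes probe baselines so leaf means are shared
within a module.

**Score.** A tree's leaves partition the cohort; all (probe, patient ∈
leaf) values in a leaf are pooled and scored by the closed-form
normal-gamma marginal likelihood with hyperparameters `(mu0 = 0,
lambda0 = 1, alpha0 = 1, beta0 = 0.1)` — a weakly informative prior on
centered log-ratios (zero mean, spread below one log2 unit). The
hyperparameters are configurable (`score_prior()`); the marginal is
verified against 2-D quadrature to 1e-8 and against the telescoping
Student-t predictive chain.

**Constraints.** Tree depth ≤ 2, ≤ 3 regulators, hence ≤ 4 patient
subgroups; each leaf keeps at least `min_leaf = 4` patients (the
smallest subgroup such studies report). Candidate thresholds are
midpoints between consecutive distinct sorted feature values, so
learned cuts sit in inter-patient gaps and recovery "within one gap"
is well defined. The left child holds patients strictly below the
threshold; displays render thresholds as range percentages with one
decimal.

**EM.** Initialization is seeded k-means on probe profiles (`K`
defaults to 50; empty modules are allowed and pruned at output). The
M-step relearns each module's tree greedily, keeping the previous tree
when the fresh one does not improve that module's score. The E-step
reassigns probes *sequentially*: each probe is removed from its module
and moved to the module with the highest leave-one-out posterior
predictive for its values (ties to the lowest index). Sequential moves
make every step score-non-decreasing, which the fitter asserts on
every iteration. A merge phase runs before and after each E-step:
module pairs are pooled whenever pooling raises the total score. The
early merge matters — k-means with `K` above the true module count
splits modules along noise directions, and once E-step sweeps have
segregated the duplicates by their noise means, the score genuinely
prefers the split, so only pre-segregation merging recovers the
planted partition. With expression fed directly to the learner,
planted modules, regulator features and thresholds are recovered
exactly (adjusted Rand index 1.0 at the default study scale). Through
the full array-processing chain, per-probe attenuation differences
create real substructure: modules then split into *pure* submodules
with equivalent trees, which is also what published module tables of
this kind show (several modules sharing identical regulator-1
thresholds), so end-to-end tests assert purity and pathway-level
recovery rather than exact partition identity.

## Pathway roll-up

Modules are annotated by probe→gene mapping, hypergeometric
over-representation against a local GMT database (`p_BH < 0.05`,
overlap ≥ 2 — the criterion is ours, standard for over-representation,
and configurable), and roll-up of altered pathways to top-level
pathways as percentages that sum to 100. The universe defaults to all
annotated array genes with a database mapping. Reporting flags mark
modules with > 10 altered pathways and dominance above 50% or 30%.

## The synthetic cohort

The generator defines the study conditions every test runs under:

* **Phantoms** (`phantom_spec()`, `make_cohort()`): 40³ grids at 2 mm
  isotropic spacing; tumors are eccentric ellipsoids (base radius 8–18
  mm) with a smooth random radial boundary perturbation (1–4 mm),
  uniform base uptake (SUV 4–9 over background 1) plus 1–5 Gaussian
  hot lumps (amplitude 2–6 SUV, width radius/3), blurred with the 5 mm
  FWHM Gaussian reconstruction post-filter and degraded with additive
  Gaussian noise (sd 0.2 SUV) truncated at zero. Noise is Gaussian,
  not Poisson: post-reconstruction PET noise is approximately Gaussian
  and the simpler model suffices for rank/range realism. Cohort MATVs
  span more than threefold; a default cohort has 45 patients.
* **Expression** (`plant_spec()`, `plant_expression()`): per-probe
  baselines N(8, 1) log2 units; planted modules add leaf-specific
  offsets driven by trees over the *extracted, normalized* phantom
  features; residual sd 0.3; raw foreground is `2^signal` plus an
  additive N(80, 10²) optical background (exercising normexp), with
  optional replicate probes. The bundled study plants 3 modules × 60
  probes over 600 null probes — a DE fraction near 20% — with leaf
  offsets (±2.6, ±1.2) so both leaves clear the fold-change filter
  with a 1.4 log2-unit between-leaf contrast.
* **Pathways** (`make_synthetic_pathway_db()`): 24 top-level families
  (mirroring the main-pathway count of the usual hierarchy), 5
  pathways each over family-private gene pools; module probes draw 80%
  of their genes from one family, making family-level dominance
  recoverable.

What the generator does *not* emulate: scanner physics (sinograms,
attenuation, reconstruction artifacts), multi-lesion anatomy, probe
cross-hybridization, batch or site effects, and correlated biological
co-regulation beyond the planted step functions. Passing tests
demonstrate that the pipeline recovers structure *of the form the
model assumes* under realistic noise — not that real tumors obey that
form.

## Problem sizes and determinism

Default test and acceptance runs use the scales above (45 patients,
40³ voxel grids, 780 probes, 3 planted modules; 5000-probe null
simulations; 100 random 4³ grids for texture oracles; 20 repeats for
pathway-dominance rates), which keep a full run in a few minutes on a
single CPU while leaving all planted effects comfortably detectable.
Every stochastic component is a pure function of an explicit seed:
phantoms and cohorts carry seeds in their specs, the EM records its
seed in the model, pipeline outputs embed a config hash, and rerunning
any stage with the same inputs reproduces its outputs byte for byte
(model JSON included). Stage outputs are cached under the output
directory keyed by that hash; the imaging stage — the slow one — is
skipped on rerun when its inputs are unchanged.

## Known limitations

* The fuzzy segmenter is a global mixture model: it inherits the
  partial-volume rim on blurred data and is not a substitute for
  locally adaptive delineation when absolute MATV accuracy matters.
* FBN texture is range-relative (see above); comparisons of normalized
  texture across tumors with very different ROI ranges need care.
* The module-network score pools probes within leaves; probe-specific
  response heterogeneity therefore legitimately splits modules, and K
  only upper-bounds the module count.
* The enrichment universe, alpha and overlap floor materially affect
  altered-pathway counts; they are explicit arguments, and pathway
  *percentages* (the roll-up) are more stable than counts.
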