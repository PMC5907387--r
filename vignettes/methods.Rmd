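---
title: "Statistical methods for paired dietary-intervention microbiome studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for paired dietary-intervention microbiome studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dogbiome)
```

# The study design this package models

`dogbiome` implements the statistical machinery for a paired dietary
intervention in dogs: each animal is profiled once on a common baseline
diet and once after four weeks on a randomly assigned intervention diet —
high-protein/low-carbohydrate (HPLC) or lower-protein/higher-carbohydrate
(LPHC) — with body condition (lean/normal, LN, vs overweight, OW) as a
second stratification. Shotgun relative-abundance profiles have a hard
*detection limit*: values below roughly 2·10⁻⁵ relative abundance are
recorded as exact zeros. Almost every analytical choice in the package
follows from taking that limit seriously.

# Censored log-ratios and the Gehan test

The per-dog response of a taxon is the log₁₀ ratio of its post-intervention
to baseline abundance, after adding a pseudo-count of one tenth of the
lowest non-zero value among the analyzed measurements. A zero is not a
measurement of zero — it is "below the limit" — so:

* baseline below the limit → the true ratio is *at least* the computed
  value: **right-censored**;
* post-intervention below the limit → the true ratio is *at most* the
  computed value: **left-censored**;
* both below the limit → the pair carries no information and is dropped
  (the count is reported).

Two diet arms are compared with the two-sided **Gehan generalized
Wilcoxon test**. Each cross-arm pair (i, j) scores +1 when observation i
is *definitely* larger (its lower bound exceeds j's upper bound), −1 in
the mirror case, and 0 when censoring leaves the order indeterminate —
including touching bounds, the conservative convention. The statistic W
is the sum of scores; its two-sided p-value comes from permuting group
membership, exhaustively when `choose(n, n1) ≤ 50,000` and otherwise by
Monte Carlo with the add-one estimator. Permutation was chosen over the
asymptotic variance because the study's subgroups are small (~16 dogs per
diet × condition cell) and because exhaustive enumeration gives an exact
oracle the test suite checks against. Log base 10 is used throughout; the
base only rescales the censored values and cannot change any rank-based
result (asserted by a test).

Across features, p-values are corrected with the **two-stage
Benjamini-Hochberg** procedure: BH at level q/(1+q) estimates the number
of true nulls m̂₀ = m − r₁; if stage 1 rejects nothing, nothing is
rejected; otherwise BH is re-run at level q·m/m̂₀ and supplies both the
rejections and the reported q-values. Because the second stage runs at a
relaxed level, q-values need not dominate the raw p-values.

# Compositional shifts, ratios and robustness

Ordination and shift analyses work on log₁₀-transformed relative
abundances with a per-feature pseudo-count (one tenth of the feature's
smallest non-zero value; a fixed global pseudo-count is available via
`pseudo_policy = "fixed:<x>"`). The per-feature scope mirrors the censored
log-ratio rule so one detection-floor convention serves the whole package.

Bray-Curtis (Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ)) is undefined on the negative values a
log transform produces, so `paired_shift()` shifts the transformed matrix
by its global minimum before computing distances. This affine shift is the
package's own choice where the construction is otherwise underdetermined;
it leaves Manhattan distances untouched and preserves the ordering
structure Bray-Curtis sees. PCoA Gower-centers the squared distances and
eigendecomposes; axes with negative eigenvalues (possible for
non-Euclidean dissimilarities) are reported but dropped, and each axis's
sign is fixed so its largest-magnitude loading is positive, making
coordinates reproducible across platforms. PERMANOVA partitions squared
distances between and within groups; besides the usual Monte Carlo
permutation p-value it offers exhaustive enumeration for two groups,
which the tests compare against brute force.

Taxon-set ratios (Firmicutes:Bacteroidetes, Prevotella:Bacteroides) are
computed from aggregated relative abundances *before* any log transform,
with one tenth of the smallest non-zero denominator added to both sums so
that identical sets give exactly 1. Group comparisons use
Mann-Whitney-Wilcoxon (two groups) or Kruskal-Wallis with all pairwise
follow-ups (three); fully tied inputs short-circuit to p = 1 rather than
propagating a 0/0 tie correction. The **leave-out robustness** procedure
re-closes the composition after removing every subset of genera up to
size 3 and re-runs the focal shift comparison, reporting the p-value range
and whether every removal stays significant — distinguishing an effect
carried by one genus from one spread over a clade.

# sparCC co-abundance networks

Closure to relative abundances induces spurious negative correlation;
sparCC estimates basis (absolute-scale) correlations from the variation
matrix t₍ᵢⱼ₎ = Var log(xᵢ/xⱼ), solving the linear system implied by
t₍ᵢⱼ₎ = ωᵢ² + ωⱼ² − 2ρ₍ᵢⱼ₎ωᵢωⱼ under the sparse mean-zero-correlation
approximation, then iteratively excluding the most strongly correlated
pair above 0.1 (up to 10 rounds) and re-solving so genuine correlations do
not bias the basis variances. Zeros are replaced by the package's standard
per-feature pseudo-count; the original method's Dirichlet resampling is
out of scope. Empirical p-values permute every taxon's samples
independently and use the add-one two-sided estimator, so p ∈ (0, 1] and a
fixed seed reproduces the matrix exactly. An edge requires *both* Spearman
|r| above 0.5 *and* a sparCC q-value (single-stage BH across all pairs —
the two-stage variant is reserved for the Gehan analyses where it is
specifically called for) at or below 5%; both statistics stay on the edge
so the dual criterion is auditable. Note the permutation count bounds the
smallest attainable p at 1/(B+1): with P pairs, BH at 5% needs B large
enough that 1/(B+1) · P is well below 0.05 times the expected edge count
(the drivers use 999).

# Marker-gene linkage groups (mOTUs)

Species-level profiles are built from ~10 universal single-copy
marker-gene families. Genes whose length-normalized, log₁₀(1+x) abundances
co-vary across all samples are linked: Pearson correlation by default
(sensitive to proportional co-variation on the log scale; Spearman is a
flag), a null distribution from independently permuting each gene's
samples, and the linking threshold set at the smallest correlation whose
empirical false-discovery estimate — expected null exceedances (add-one)
over observed exceedances — stays at or below 0.02. Supra-threshold edges
are agglomerated strongest-edge-first under the single-copy constraint:
a group never contains two genes of one family, so sizes fall in [2, K]
by construction; singletons are discarded. Group abundance is summed
member counts over summed member lengths, closed per sample; the
per-sample detection limit is the least-abundant group's relative
abundance and the global limit is the largest (least sensitive) of these.
Taxonomy migrates to a group only at ranks where every member gene agrees,
with species additionally requiring each member's identity to exceed its
family's clustering cutoff.

# Dual-search LCA annotation

Gene-level taxonomic annotation runs a homology search; if the best
e-value exceeds 10⁻⁵ the gene is a no-hit. Otherwise the best hit's
matched subject region seeds a second search, and all second-search hits
with e-value at or below the first search's best e-value (the only scalar
the first stage produces) form the homolog neighborhood, whose lowest
common ancestor is assigned. The seed subject belongs to its own
neighborhood — it trivially satisfies the e-value condition. Ties for the
best first-stage hit break by subject id so annotation is deterministic.
Search backends are injected functions (the tests use precomputed hit
tables), so no aligner is required.

# Diet classification and strain distances

Diet predictability is estimated by leave-one-out cross-validation of a
ridge-penalized logistic regression (L2 is the least-assumptive reading of
"penalized"; lasso via `alpha = 1`). For each held-out sample the features
are rank-normalized *on the training samples only* — average ranks scaled
to (0, 1], held-out values linearly interpolated into the training
distribution and clipped at its extremes — and the penalty is chosen from
a 7-point log-spaced grid by stratified 5-fold inner CV on the training
set alone. Classes receive balanced weights in every fit: without them,
leave-one-out's one-sample class imbalance biases the intercept against
the held-out sample's class and drags null AUCs far below 0.5 (the
"anti-learning" artifact); with them, permuted-label AUCs settle near
chance. AUC is the trapezoidal integral of the threshold-swept ROC and
equals the Mann-Whitney concordance probability, which the tests assert on
random instances.

Strain-level comparisons gate samples at 5× mean depth and 80% genome
breadth, then take the mean absolute allele-frequency difference over
positions observed in both samples — 0 for identical profiles, 1 for
completely distinct ones. Pairs sharing fewer than 50 positions (a
configurable floor) are declared incomparable rather than silently
estimated from noise; multiallelic positions are assumed collapsed to the
major-allele frequency upstream.

# The synthetic-study generator

`simulate_study()` is first-class, tested code that defines the study
conditions: 64 dogs of two breeds, half OW; baseline log₁₀ taxon means
drawn Normal(0, 1.6) — a long-tailed abundance distribution under which
roughly half the censored matrix sits below the 2·10⁻⁵ limit, matching the
sparsity regime the censored methods target; a per-dog, per-taxon random
effect (SD 0.5 log₁₀) shared between the two timepoints; per-sample noise
(SD 0.3); and planted log₂ fold changes concentrated on named genera, with
the HPLC arm carrying the strong effects and OW dogs on HPLC realizing
effects with doubled mean and variance (`ow_response_multiplier = 2`).
Each dog draws its own effect around the planted value (SD 0.4 log₂), so
subgroup response *variability* is a real, recoverable signal. The
detection limit is applied to the *relative* abundances after closure,
because that is the scale on which such limits are defined. The defaults
were fixed once, from the design being emulated, and are what the
acceptance checks run against.

What the generator does **not** emulate: sequencing depth variation and
count noise (abundances are continuous), compositional correlation beyond
closure, breed- or sex-specific effects, temporal drift between cohorts,
and real phylogenetic correlation among taxa. Passing tests therefore
demonstrate that the estimators recover what was planted under a
log-normal, detection-limited regime — not that any particular real
dataset will behave as cleanly.

`maintenance_energy()` records the feeding rule: MER = 139 × BW^exponent
kcal/day. The allometric exponent defaults to the conventional 0.75 and is
deliberately configurable rather than hard-coded.

# Numerical choices and degenerate inputs

* Pseudo-counts: per-feature minimum non-zero / 10 everywhere; an all-zero
  feature falls back to the global minimum / 10 with a warning.
* Gehan: exhaustive enumeration up to 50,000 splits; ties/touching bounds
  score 0; Monte Carlo p-values use the add-one estimator and are never 0.
* Two-stage BH with stage-1 rejections r₁ = 0 rejects nothing; m̂₀ = 0
  rejects everything.
* PCoA eigenvalues within 10⁻¹⁰ of zero are treated as zero; exact-zero
  distance matrices return all-zero coordinates.
* Kruskal-Wallis / Wilcoxon on fully tied ratios return p = 1 explicitly.
* sparCC basis variances that solve negative are clamped to the smallest
  positive solution before the correlation back-substitution, and
  correlations are clipped to [−1, 1].
* All stochastic entry points take explicit seeds and restore the caller's
  RNG state; the pipeline derives fixed per-stage offsets from its base
  seed, so disabling one stage cannot shift another stage's stream.

# Problem sizes used by the checks

The test-suite and acceptance drivers run the full 64-dog, 96-taxon
default study; method-level calibrations use 500 null replicates for the
Gehan type-I rate (n = 20+20, ~30–50% censoring), 20 seeds of 20 taxa ×
500 samples for sparCC recovery, 30 species × 10 families for linkage
recovery, and 999-permutation networks over the 12-genus panel. These
sizes were chosen to make Monte-Carlo error small relative to the margins
being asserted.

# Known limitations

The Gehan permutation test assumes exchangeability across dogs within
arms and ignores covariates; censored regression is out of scope. The
sparCC implementation omits Dirichlet resampling, so its p-values reflect
permutation nulls only. The linkage FDR is an empirical permutation
construction — the threshold, not the grouping algorithm, is the
calibrated quantity. Unifrac/phylogenetic distances and multiclass diet
classification are extension points, not features.
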