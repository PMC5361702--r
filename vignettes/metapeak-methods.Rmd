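---
title: "metapeak: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metapeak: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapeak)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
choices made where the design was genuinely open.

## The data model

A `peak_table` is a features × samples matrix of chromatographic peak
intensities with per-feature m/z (Thomson), retention time (minutes) and
an optional adduct annotation string. Missingness is first-class: an
undetected peak is `NA`, never a zero or other sentinel, because exporters
disagree on how they encode dropouts and because downstream statistics
must be able to distinguish "absent" from "small". On reading, empty
cells and `"NA"` are always missing and exact zeros are treated as missing
by default (`zero_as_missing = TRUE`) — the common exporter convention for
undetected peaks; the flag exists because some pipelines do emit true
zeros.

Sample metadata carries `batch`, `class` and the injection `order`. A row
with an empty class is a pooled QC injection (`is_qc = TRUE`). Everything
QC-related in the package — drift correction, the CV filter, the QC
correlation chart — keys off this flag.

## Pre-processing

**Detection filter.** A feature is dropped when detected in fewer than
50% of QC samples *or* fewer than 20% of experimental samples (both
fractions configurable; comparisons are strict, so exactly 20% survives).
The rationale: a peak the pooled QC misses half the time is not
quantifiable, whatever the biology. With no QCs only the sample rule
applies.

**Imputation.** Four estimators with different bias profiles:

* `knn` (default k = 10): each missing cell is the mean, in that sample,
  of the k nearest features by Euclidean distance over co-observed
  samples. Imputing across features rather than samples is the usual
  omics choice — feature co-regulation is a stronger signal than sample
  similarity when samples span biological groups.
* `svd`: iterative rank-3 reconstruction, initialised at feature means,
  iterated to a relative Frobenius change below 1e-6 (at most 100
  iterations).
* `rf`: iterative random-forest regression per incomplete feature
  (most-complete first), missForest-style stopping when the change in
  imputed values stops decreasing; seeded, so bit-reproducible.
* `min_half`: half the feature's observed minimum — the left-censoring
  surrogate appropriate when dropouts are intensity-dependent, and the
  cheapest option for large tables.

`bpca` is a reserved name that raises a not-implemented error: Bayesian
PCA imputation is a project of its own, and silently mapping the name to
a different estimator would be worse than refusing.

Observed cells are never altered by any method.

**Transforms and scaling.** `glog(x) = log2((x + sqrt(x² + λ))/2)` with
λ defaulting to the square of the smallest positive observed intensity —
behaving like log2 for large x while staying finite at zero. Scaling is
feature-wise after transformation; the multivariate preset used
throughout is glog + Pareto (`(x−m)/√s`), which tames the dominance of
high-abundance features without the noise amplification of full
autoscaling.

**Outlier removal.** Iterative Hotelling-T² screening on a 2-component
PCA score plot: sample i is outlying when
`T²ᵢ = t₁ᵢ²/s₁² + t₂ᵢ²/s₂² > expand² · 2(n−1)/(n−2) · F(conf; 2, n−2)`,
with removal and refitting for up to three rounds (stopping early when a
round removes nothing). `conf = 0.95` and `expand = 1` are defaults and
both are exposed: the ellipse-expansion factor is a judgement call with
no canonical value, so it is a flag rather than a constant.

## Normalization

Sample-based methods correct per-sample dilution: total-sum (rescaled to
the median total so the intensity scale is preserved), PQN (reference =
feature-wise median over QCs when at least two exist, else over all
samples — QC anchoring matches the QC-centric design; an explicit
reference can be supplied), and quantile (rank/mean substitution,
mean-of-tied-ranks for ties; incomplete samples interpolate the reference
at their observed quantiles and missing cells stay missing). `vsn` is a
reserved not-implemented name for the same reason as `bpca`.

**Drift correction.** Both QC-based corrections share one engine: per
feature (and per batch), fit the QC log-intensities against injection
order, subtract the fitted curve from *all* samples on the log scale, and
re-anchor to the feature's overall QC median:

    corrected = exp(log x − fit(order) + median(log x_QC))

Working in log space makes multiplicative drift additive; anchoring to
the *global* QC median (not the per-batch one) lets per-batch curves also
remove batch-to-batch offsets. Division by the fitted curve on the raw
scale is the algebraically equivalent formulation.

* `qcrsc_correct` uses a cubic smoothing spline; the penalty is chosen
  per curve by exact leave-one-out CV (the leverage identity, so no
  refitting) over 20 log-spaced candidates spanning `10^-4`–`10^2`, with
  near-ties resolved toward the smoother fit — under-smoothing chases QC
  noise and reinjects it into the samples.
* `svr_correct` uses ε-SVR with an RBF kernel (ε = 0.1, cost 1, inputs
  scaled), which tolerates occasional aberrant QC points better than a
  spline.

Predictions are clamped to the injection-order range spanned by the QC
points — extrapolating a spline beyond its support is how corrections
blow up at run boundaries. A feature/batch with fewer than `min_qc = 4`
observed QC points falls back to QC-median scaling (a constant curve),
with a message.

**Batch correction.** `combat_correct` implements the empirical-Bayes
location/scale adjustment on log intensities: standardize per feature,
estimate per-batch/feature location γ and scale δ², shrink toward
parametric priors (normal for γ, inverse-gamma for δ², hyperparameters by
method of moments) through the standard fixed-point iteration, adjust and
back-transform. It is NA-aware — every mean and variance is computed over
observed cells — which is why it is implemented in-package; the tests
cross-check it against an independent implementation on complete
matrices. Note the EB shrinkage is a deliberate bias: with few features
or heterogeneous within-variances, per-feature batch means are *not*
exactly equalized.

**CV filter and comparison.** After normalization, features with QC CV
above 30% (configurable, `≤` passes) are dropped. CV is reported as a
fraction internally and only rendered as percent. The comparison table
applies each candidate method plus the mandatory `"none"` baseline to the
same input and reports peak counts, QC-CV pass counts, per-group mean CV
and DEF counts, so the method choice is an explicit, data-driven step.

## Statistics

**Univariate.** Per feature: Welch t (pooled by flag — with unequal group
variances common in intensity data, Welch is the safer default),
Mann-Whitney U (exact enumeration when n₁+n₂ ≤ 12 and untied, else the
normal approximation with continuity and tie corrections), BH q-values
computed per test family, fold change on the normalized raw scale
(case/control in the order given), and the pair-counting ROC AUC (ties ½).
QC samples are always excluded; a feature with fewer than two observed
values in a group is reported untestable rather than guessed at.

**DEF selection** uses q ≤ 0.05 AND (FC ≥ 1.5 OR FC ≤ 1/1.5) AND
VIP ≥ 1. Fold changes and the reciprocal bound are compared after
rounding to three decimals, matching the field's reporting convention in
which the lower bound is printed as 0.667 and a feature at exactly 0.667
is selected. The default q comes from the Mann-Whitney family (the
t-family is a flag): the rank test's robustness fits typically skewed
intensity distributions. The VIP attached to univariate results comes
from a 2-component PLS-DA on the glog + Pareto version of the same table.

**Multivariate.** PCA by SVD. PLS-DA is PLS1 via NIPALS on a −1/+1
response; R²Y is explained response variance on the fit, Q²Y the
cross-validated analogue from seeded stratified k-fold (default 7)
prediction, and `VIP_j = sqrt(p · Σ_a SSY_a w²_aj / Σ_a SSY_a)`, which
fixes mean squared VIP at exactly 1 — the identity the tests assert on
every fit. OPLS-DA removes `n_orthogonal` response-orthogonal components
by the standard O-PLS deflation before fitting one predictive component;
with one of each this is the usual two-component model, and on data with
no orthogonal structure the predictive component coincides with PLS1.
The permutation test refits under `n_perm` label permutations and reports
`p = (1 + #{Q²Y_perm ≥ Q²Y_obs}) / (1 + n_perm)` — the +1 smoothing keeps
p away from an unattainable zero, so the minimum is `1/(n_perm+1)`.

A note on ceilings: a single informative feature with a d-sd group shift
and unit noise can explain at most `d²/(d²+4)` of a ±1 response's
variance (≈ 0.86 at d = 5), however good the model; Q²Y expectations
should be calibrated against that, not against 1.

**Power.** `estimate_power` is a deliberately light projection, not a
full effect-size deconvolution: π₀ by the Storey median estimator
(`min(1, #{p > 0.5}/(m/2))`), the `(1−π₀)·m` largest |t| converted to
standardized effects `d = t·√(1/n₁+1/n₂)` (uncorrected — simple and
transparent, at the cost of optimism from selection bias), and for each
candidate n the average two-sided two-sample noncentral-t power over that
effect set. With no estimated non-nulls the curve sits at α.

## Networks

Correlation networks test all feature pairs (Pearson default, Spearman
available) over pairwise co-observed samples, requiring at least 5 shared
observations per pair — below that a correlation estimate is mostly
noise. P-values come from the t-transform; the differential network
compares groups with the Fisher z statistic and a standard-normal
two-sided p; both adjust the *whole tested family* by BH and keep edges
at q ≤ 0.05 (correlation) / q ≤ 0.01 (differential). Correlations of
magnitude 1 are clipped to 1 − 1e-12 before `atanh`. Centralities follow
the component-wise conventions (closeness = (reachable−1)/Σ distances,
0 for isolated nodes; betweenness unnormalized). Community detection is
fast-greedy modularity maximization; the merge tree is cut at maximum
modularity with near-ties (within 1e-10) resolved toward fewer
communities, which makes the partition deterministic and immune to
floating-point noise in the merge path. GML export carries node
attributes; Pajek carries the vertex/edge lists.

## Identification

Neutral mass is `M = mz·charge − mass_shift` with electron-corrected
shifts to five decimals ([M+H]⁺ 1.00728, [M+Na]⁺ 22.98922, [M+K]⁺
38.96316, [M+NH₄]⁺ 18.03383, [M−H]⁻ −1.00728). Matching retrieves every
compound with `|delta_ppm| ≤ tol` (default 10 ppm) by binary search over
the mass-sorted database; `delta_ppm = (inferred − db)/db × 1e6`, positive
when the observation is heavier. When annotations are honoured, an
annotated feature tries only its own adduct and isotope-annotated peaks
(e.g. `[M+1]+`) are skipped — they are not monoisotopic and would only
generate false hits.

## Biomarker selection

Backward RFE: starting from all features, rank by estimator importance
(random forest: mean impurity decrease over 500 trees, √p features per
split; linear SVM: |hyperplane weight|), cut down to each candidate size
(default schedule halves the count), and score each size by seeded
stratified k-fold (default 5) cross-validated ROC AUC. The best size is
the maximum mean AUC with ties resolved toward the *smaller* panel —
parsimony is the point of the exercise. Held-out evaluation accepts
either a per-class training fraction or explicit sample lists (so a
published split can be mirrored exactly), and reports the threshold-sweep
ROC plus the pair-counting AUROC. The "5-fold" CV sits *around* the
elimination loop, the standard arrangement; nesting it inside each
elimination step would multiply cost without changing the selection
contract.

## The synthetic-data generator

`simulate_peak_table` emulates exactly the structures the pipeline
claims to handle, with ground truth recorded: log-normal base abundances
(log2 means uniform in [10, 20], technical noise sd 0.2 log2 units),
cases and controls shuffled through a single injection sequence across
(default) 2 batches, a pooled QC every 5 positions whose profile is the
pool mean plus the same measurement noise, multiplicative drift along
injection order (half-sine or linear, relative amplitude 0.3 by default),
N(0, 0.5²) per-feature log2 batch offsets, 50 differential features
shifted by 1 log2 unit in cases, and intensity-dependent dropout
(logistic in log2 intensity, slope 1, centred 2.5 feature-mean sds below
the abundance centre — faint peaks vanish first, which is what the
detection filter and `min_half` imputation are for). Identical parameters
and seed give bit-identical output.

What it does *not* emulate: correlated feature blocks from shared
metabolic origin, adduct/isotope degeneracy of real peak lists, retention
time shifts, heteroscedastic noise across the intensity range, or
non-monotone within-batch drift. Tests that pass on this generator
therefore certify the algorithms against their stated model —
drift-shaped technical variation, additive batch offsets on the log
scale, MNAR dropout — not against every pathology of real instrument
data.

Test and verification problem sizes are chosen to exercise the estimators
at realistic dimensionality while keeping the whole suite fast: up to
1000 features and 40 + 40 samples for pipeline-recovery runs, 10,000
features for the type-I error simulation, 20 seeds for the RFE recovery
rate, 200 replicates at 50 permutations for the null-uniformity check.

## Reporting and determinism

The HTML report inlines everything (no external assets) and contains no
timestamps; two runs on identical inputs produce byte-identical files,
verified by test. Every stochastic routine takes an explicit seed and is
reproducible bit-for-bit under it; nothing in the package reads the
global RNG state without setting it.

## Known limitations

* PLS-DA/OPLS-DA are strictly two-class; multi-class designs need
  one-vs-rest orchestration outside the package.
* The EB batch correction assumes log-scale location/scale batch effects;
  batch-by-group confounding is not modelled (no covariate design
  matrix).
* The power projection inherits selection bias from thresholding pilot
  statistics; treat its curves as planning guidance, not guarantees.
* `bpca` imputation and `vsn` normalization are reserved names, not
  implementations.
* Identification is mass-only: isomers are indistinguishable and hits are
  putative by construction; MS/MS evidence is out of scope.
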