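---
title: "Methods: promoter nucleosome-footprint profiling of cfDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter nucleosome-footprint profiling of cfDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promfoot)
```

## The measurement model

Plasma cfDNA fragments are the remnants of nuclease digestion of
apoptotic chromatin: DNA wrapped around nucleosomes is protected, linker
and nucleosome-free DNA is lost. Read coverage over a promoter window
therefore encodes promoter activity in the contributing tissues — in
pregnancy, chiefly placenta and maternal blood. The unit of analysis is
the **pTSS**: the window `[tss − 1000, tss + 1000)` around each
transcript's start site, 2,000 bp exactly.

Conventions, fixed once and used everywhere:

* Coordinates are 0-based half-open (the BED/genePred convention); the
  TSS of a − strand transcript is `txEnd − 1`. The window is
  `[tss − 1000, tss + 1000)` on both strands — orientation matters only
  when per-base profiles are computed, where − strand windows are
  reversed so that negative offsets are always upstream. Because the
  even-length half-open window is asymmetric by one base around the TSS,
  exact mirror symmetry between strands holds up to a 1-bp shift; this
  is a property of the convention, not an error, and is pinned by a test.
* Fragments (sequenced template intervals), not reads, are the counting
  unit; a fragment counts toward every region it overlaps by ≥ 1 bp.
  Duplicate removal is assumed done upstream.
* Normalized coverage is fragments per kilobase per million mapped
  fragments, `raw / ((L/1000)(total/10⁶))`. The choice of a
  depth-normalizing constant is immaterial for the rank-based
  differential statistics (any per-sample monotone rescaling common to
  all samples leaves p-values unchanged — asserted by test); it does
  affect log₂ fold changes, which is why one convention is recorded in
  the `normalization_tag`.

## Differential coverage

Per gene, groups are compared with the two-sided Wilcoxon rank-sum test;
p-values are BH-adjusted, and a gene is called differential at the dual
gate |log₂FC| ≥ 1 and FDR ≤ 0.05, with log₂FC = log₂(mean preterm /
mean term) so that "up" means more coverage (more protection) in the
preterm group. Exact-null branches are used where they are standard
desk-scale practice: rank-sum enumeration when the pooled sample size is
≤ 12 with no ties, signed-rank enumeration up to 25 non-zero
differences; beyond that, the tie-corrected normal approximation with
continuity correction (at 20 + 20 samples only the approximation is
standard practice). A term-group mean of zero makes log₂FC infinite;
for tabulation it is replaced by `sign · (max finite |log₂FC| + 1)` —
the call is decided by FDR and direction, so this substitution only
affects plotting.

Gene-set footprint contrasts compare each sample's mean coverage over
one gene set against another (paired, signed-rank across samples) or one
set's per-sample mean between clinical groups (unpaired, rank-sum).
With 20 paired differences that all share one sign the exact two-sided
signed-rank p reaches its floor 2/2²⁰ ≈ 1.9e−06 — the strongest
statement the test can make at that cohort size, and a useful fixed
point for validation.

## Discretization, importance, pruning

Each called gene is dichotomized at the cutoff maximizing the
dichotomized feature's AUC = (Se + Sp)/2 on the training cohort,
candidates being midpoints between consecutive distinct values, ties
resolved toward the smallest cutoff; the better of the two orientations
is recorded (`case_high` / `case_low`) but the encoding is always
`value > cutoff` → 1. Importance is ranked by linear SVM-RFE
(iteratively eliminate the feature with the smallest squared weight of a
linear maximum-margin fit; rank = reverse elimination order), which
supplies the total ordering the later stages consume. Correlation
pruning then walks the ranking from most to least important and drops
any feature whose |Pearson r| with an already-kept feature exceeds 0.5,
computed on the discretized matrix — matching the stated stage order
(discretize → importance → prune). The retained set provably contains
no pair above the threshold and every dropped feature conflicts with a
kept one (a maximality property pinned by test).

By default the cutoffs, ranking and pruning are computed once on the
full training cohort before any cross-validation — the published
procedure order, which leaks information into resampled error estimates.
This "faithful" mode is the default because reproducing the procedure is
the point; a leakage-safe LOOCV variant recomputes cutoffs inside each
fold, and a test checks it is no more optimistic than faithful mode on
null data, on average.

## Classifiers and evaluation

Four families are supported — linear/RBF SVM (`e1071`), logistic
regression (`glm`, with a ridge fallback under separation), random
forest (`randomForest`), XGBoost (`xgboost`) — with hyperparameters for
the latter two chosen by grid search over documented grids (RF: 500
trees, mtry ∈ {√p, p/3, p/2}; XGB: depth {2,4,6} × η {0.05,0.1,0.3} ×
rounds {100,300}) using cross-validated AUC. Feature selection is
either greedy backward elimination — delete the feature whose removal
most increases the stratified 10-fold CV AUC, stop when no deletion
strictly improves, return the subset at the global maximum of the trace
with ties resolved toward fewer features (the stopping rule is this
package's choice; any published description leaves it open) — or lasso
(λ maximizing 10-fold CV AUC, non-zero coefficients retained).

Evaluation: AUC is the Mann–Whitney pair statistic with ties counted ½.
CV AUC pools out-of-fold scores into a single AUC (the pROC-compatible
convention) rather than averaging per-fold AUCs — with two cases per
fold at desk scale, per-fold AUCs would be too unstable to be
meaningful. LOOCV refits n times and evaluates the held-out scores;
confidence intervals and paired model comparisons use DeLong structural
components (implemented here, cross-checked against `pROC` in the test
suite). The operating threshold for sensitivity/specificity/accuracy is
the Youden-optimal point on the held-out scores, and recall is the
sensitivity for the preterm class; where an operating point is not
otherwise specified this is the standard neutral choice.

## What the synthetic cohorts emulate

`simulate_coverage_cohort()` draws, for sample *s* and gene *g*,

```
coverage[s, g] = exp(N(mu_g, baseline_log_sd)) * m[s, g] * exp(N(0, sample_noise_log_sd))
mu_g           = baseline_log_mean - expression_slope * percentile_g
m[s, g]        = 1 + ff_s * (2^(sign_g * lfc) - 1)   for planted genes in preterm samples
```

so the planted log₂FC is exactly the asymptotic log-ratio of group
means (verified against a 2,000-per-group law-of-large-numbers test) and
fetal fraction acts as a mixture weight on the placental signal when
`ff_attenuation = TRUE`. Defaults define the reference study
conditions: 20 + 20 samples, 1,000 genes, 60 planted at |log₂FC| = 1.2
with the effect at full strength, lognormal noise with
`baseline_log_sd = sample_noise_log_sd = 0.25` (combined CV ≈ 36%, a
realistic scale for normalized promoter coverage at low-pass depth),
`baseline_log_mean = log(10)` and `expression_slope = 1` (a fully
expressed promoter has e-fold lower coverage — enough to make the
composite footprint contrast deterministic in direction at 500-gene
sets). BMI ~ N(22, 3²) kg/m² and fetal fraction ~ Beta(10, 90) (mean
0.10) are drawn identically for both groups by default, so standalone
clinical AUC is 0.5; small location shifts (`bmi_shift`, `ff_shift`)
reproduce a weakly informative ≈ 0.53 regime when wanted.

Both noise terms are independent per sample-and-gene cell — a
biological and a technical component. This matters: a noise factor
*shared* across genes within a sample would make per-gene rank tests
conditionally miscalibrated within a cohort (the same sample ordering
tendencies recur in every gene), and the generator is required to be
exactly calibrated under the null so that calibration failures observed
downstream indicate real defects.

The fragment-level generator places fragment midpoints by a
cosine-phased nucleosome occupancy (period 190 bp, amplitude 0.5) with a
nucleosome-depleted region at oriented offsets −150..+49 scaled by
`1 − percentile · (1 − ndr_depth_factor)`; the NDR window position
(just upstream of the TSS) is a free modelling choice within the known
biology. Total fragment yield per region scales with the region's
occupancy mass, so depleted (expressed) promoters also yield fewer
fragments — the footprint as seen in coverage, not just in shape.
Fragment lengths are N(167, 20²) bp truncated to [50, 400], centred on
the mononucleosome peak.

Not emulated: GC bias (the GC reweighting step is therefore OFF by
default), mappability and alignment artifacts, maternal genotype,
sequencing error, fragment-end motifs, and any real biological
correlation structure among genes. Passing recovery tests on these
cohorts demonstrates that the pipeline's statistics and selection logic
behave as designed — not that the classifier would attain comparable
AUCs on real plasma cfDNA, where effects are weaker and correlated.

## Calibration testing of discrete tests

The rank-sum statistic at 20 + 20 is discrete (401 support points), so
its p-values cannot be exactly uniform: even exact-test p-values fail a
naive Kolmogorov–Smirnov uniformity check at large pooled counts, with
the KS distance converging to the largest point mass (≈ 0.022) rather
than to zero. Null calibration is therefore assessed on the randomized
probability integral transform `u = F(W−1) + U · f(W)` (with `F`, `f`
the null CDF/pmf of the rank-sum statistic), which is exactly
Uniform(0,1) when the null holds, plus a direct check of the empirical
rejection rate at α = 0.05. This is the standard way to test
calibration of a discrete test; a raw-p KS check would reject any
implementation, however correct.

## Problem sizes in the test suite

The suite runs the default cohort (20 + 20 × 1,000 genes) across 10
seeds for both the null-calibration and planted-recovery experiments,
500 simulations at n = 200 for DeLong CI coverage, and a 4,000-draw
permutation oracle for the paired DeLong test — sizes chosen so each
property is measured with useful precision while the whole suite stays
interactive (≈ half a minute).

## Known limitations

* The faithful-leakage default reproduces a procedure that overstates
  resampled performance; use `leakage = "safe"` for honest error
  estimates on your own data.
* The discovery rank-sum test assumes exchangeable samples within
  groups; batch or cohort effects must be handled upstream.
* The chrY fetal-fraction estimator applies only to male-fetus
  pregnancies and needs calibrated male-reference and female-background
  proportions.
* Backward elimination is O(p²) cross-validated fits; for panels much
  beyond ~10² features after pruning, prefer lasso selection first.
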