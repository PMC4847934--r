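---
title: "Models and methods: cross-decoding awake offline memory reactivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: cross-decoding awake offline memory reactivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reactivatr)
```

## The scientific question

After a learner encodes new paired associates, does the brain keep working
on them "offline" - without rehearsal - while the learner performs an
unrelated task? One way to ask this with fMRI is cross-decoding: train a
classifier to distinguish the distractor-task vocabulary period (when
offline processing of just-encoded pairs could occur) from an independent
vocabulary period (identical task, no preceding encoding), and then apply
that classifier to the encoding-period volumes. If encoding-period activity
patterns are preferentially classified as "distractor-condition", the
patterns present at encoding are being re-expressed during the
post-encoding distractor period - reactivation.

`reactivatr` implements this analysis end to end - functional localizer,
pattern extraction, linear-SVM decoding scored as d', cross-decoding, a
temporal-proximity control, behavioural comparisons, and nonparametric
group inference - together with a synthetic-session generator that plants a
reactivation signal of known strength, so every stage can be validated
against ground truth without any real data.

## The simulated session

One functional run of 528 volumes at TR 2.5 s (1320 s). The run contains,
in one of two counterbalanced orders: two distractor-task conditions
(instruction 5 s, encoding 120 s, instruction, distractor vocabulary 120 s,
instruction, probe 80 s with 16 forced-choice trials, 5-s bonus screen),
one immediate-recall condition (the same without the vocabulary segment),
two independent vocabulary tasks (instruction + 120 s), and one 60-s trivia
block; a 15-s fixation precedes every task and fixation ends the run. The
itemised segments total 1310 s; the remaining 10 s are assigned to the
trailing fixation so that the blocks tile the run exactly. Epochs are
half-open intervals `[onset, onset + duration)`; voxel indices are 1-based
(R convention) and world coordinates come from the affine.

### Forward model

Each voxel's time series is

> baseline
> + beta_enc * cluster(v) * X_enc(t)
> + a_voc * p(v) * X_vd(t)
> + rho * a_voc * p(v) * X_enc(t)
> + drift * (vol - 1) + noise,

where `X_enc` and `X_vd` are the encoding and distractor-vocabulary
boxcars convolved with the canonical double-gamma HRF (gamma shapes 6 and
16, unit scales, undershoot ratio 1/6; regressors are normalised by the
HRF integral so a sustained epoch plateaus at its nominal amplitude), and
`p` is a unit-norm, zero-spatial-mean pattern vector over a 15-mm sphere.
Noise is white Gaussian by default (`noise_sd = 1`), optionally AR(1) with
the innovation variance scaled so the marginal SD stays `noise_sd`
(`ar1_phi = 0.3` is a realistic optional setting). Linear drift is the
supported drift form; its default slope is 0 because the pipeline
deliberately omits the high-pass filtering a preprocessing stream would
apply, and the decoding path is drift-immune anyway (see centering below).
Motion regressors are smoothed Gaussian noise passed downstream as given
covariates; no realignment is simulated.

Defaults (`sim_config()`): 35 subjects, alternating counterbalance orders;
`beta_enc = 5` (univariate cluster amplitude, in units of the noise SD) in
four radius-2 clusters at the quarter-points of the grid; `a_voc = 1`,
`rho = 0.6`, `noise_sd = 1`. Behavioural responses are Binomial(16, 8.73/16)
and Binomial(16, 7.94/16) probe scores for the distractor and
immediate-recall conditions, Binomial(15, 7.41/15) vocabulary scores, and
Gaussian per-subject mean reaction times (4.25 +/- 0.68 s vs
4.16 +/- 0.57 s), emulating the magnitudes such a study reports.

### Why the pattern sphere is disjoint from the univariate clusters

A deliberate geometric choice: the sphere carrying the multivariate pattern
(default: grid centre) does not overlap the planted univariate clusters.
The pattern is zero-mean across voxels, so the pattern region carries
distributed information with no univariate activation - the textbook MVPA
situation. The converse matters more: a strong univariate encoding
activation map *inside* a decoding ROI projects onto the (noise-perturbed)
vocabulary discriminant with a random sign per subject, adding a symmetric
per-subject offset of order `beta_enc` to every encoding volume's decision
value. That offset cannot be removed within a subject: orthogonalising the
discriminant to the subject's estimated encoding-activation map, or
temporally centering the encoding test set, removes the sustained planted
reactivation identically, because both are spatially fixed encoding-locked
maps and are indistinguishable from a single subject's data. What
distinguishes reactivation is purely its across-subject consistency
*along the discriminant direction* - which is exactly what the group test
measures. Keeping the planted univariate and multivariate signals spatially
separate therefore lets one calibration target (localizer recovery) and the
other (reactivation power) be validated without confounding each other.
With real data the same geometry issue would manifest as reduced power, not
bias: the offset is symmetric, so the one-tailed group test stays valid.

## Localizer

The localizer path smooths each 4D image with a separable Gaussian kernel
(FWHM 8 mm; sigma = FWHM / (2 sqrt(2 ln 2)) per axis, truncated at 4 sigma
and renormalised so constants are preserved, including at boundaries), fits
a first-level GLM per voxel (one HRF-convolved epoch regressor per task
condition, six motion regressors, intercept; fixation is the implicit
baseline), and takes the encoding > baseline contrast. Second level is a
voxelwise one-sample t-test across subjects (dof = n - 1; zero-variance
voxels are flagged and dropped from the mask). Familywise error is
controlled by Bonferroni over in-mask voxels - a conservative,
dependency-free choice relative to random-field thresholds; with
well-separated synthetic blobs the difference is immaterial. Suprathreshold
voxels are grouped with 26-neighbour connectivity (the choice is stated for
determinism; synthetic blobs are far apart), clusters must exceed 20 voxels
(`size_k > k_min`), and each surviving peak is wrapped in a 15-mm
(5-voxel-radius, 515-voxel) sphere ROI. Thresholding is one-sided because
the contrast of interest is an activation.

## Pattern extraction and centering

MVPA consumes unsmoothed, non-deconvolved data. For each 120-s vocabulary
block the first 10 s (4 of 48 volumes) are excluded for hemodynamic lag,
leaving 44 volumes per block; encoding epochs get the same exclusion for
consistency (the choice is configurable via `lag_exclude_s`). A volume
belongs to a block if its acquisition start time falls in
`[onset + lag, onset + duration)`.

The four vocabulary blocks of a subject are pooled per ROI and
double-centered: each voxel's mean across the pooled volumes is removed,
then each volume's mean across voxels. Pooling across the blocks entering
the analysis (rather than per block) means train and test folds share a
single affine shift and no per-block information leaks into the fold
structure. Row (across-voxel) centering removes spatially uniform
components - baseline, drift, global activation shifts - which is why the
decode path is immune to the drift term.

Cross-validation uses the block structure: with two blocks per class, all
four one-block-per-class train/test combinations are evaluated (88 training
and 88 testing patterns each, at the default geometry), and the subject's
d' is the mean over the four folds. Evaluating all four splits rather than
a single one removes the arbitrariness of choosing a particular split; the
per-fold results are retained in the output.

## Decoding and scoring

The classifier is a soft-margin linear SVM (libsvm via `e1071`) at fixed
`cost_C = 1` - no tuning, no scaling, features are voxels. The fitted model
is reduced to an explicit weight vector and bias; decision ties (exactly
zero) go to the negative (independent) class, a deterministic and
conservative rule. Fold performance is scored as sensitivity:
`d' = qnorm(HR) - qnorm(FA)`, with rates clipped to
`[1/(2N), 1 - 1/(2N)]` so perfect folds stay finite
(`d' = 2 qnorm(87/88)` for a perfect 44/44 vs 0/44 fold).

### The cross-decoding threshold

For the reactivation test a single SVM is trained on all four
double-centered vocabulary blocks and applied to every retained encoding
volume. Encoding test patterns receive only across-voxel centering, and by
default the decision threshold is placed at the fixation-baseline origin
along the discriminant axis (`threshold = "baseline"`: the fitted bias,
which locates the between-class midpoint of the vocabulary data, is
dropped). The test then asks, volume by volume: does this encoding pattern
lie on the distractor-condition side of baseline along the direction that
separates the two vocabulary contexts?

This choice is the pivotal numerical decision of the package, so its
rationale is spelled out. The two natural alternatives both fail the
test's own calibration requirements under a sustained reactivation signal:

* temporally centering the encoding test set on its own voxel means
  removes any sustained encoding-locked component - including the
  reactivation being tested for - so the measured proportion is pinned at
  chance for every reactivation strength;
* keeping the trained bias (the vocabulary-class midpoint) shifts the null:
  encoding volumes with *no* reactivated component sit at the independent
  class's position, half a class-separation away from the midpoint, so the
  expected proportion under the null is well below 50%.

With the baseline-referenced threshold, encoding volumes without a
reactivated component have, in expectation, no projection on the
discriminant: the proportion classified as distractor-condition is 50%
exactly in law under the null (the package verifies a grand mean within
0.5 +/- 0.02 over 200 null cohorts), and it rises monotonically with the
planted reactivation strength. `threshold = "trained"` is available for
the conventional rule; in that mode the test set is first projected into
the training frame (training column means applied) so the bias is the
genuine midpoint.

The subject's reactivation score is the fraction of encoding volumes
labelled distractor-condition, pooled over the encoding epochs in scope.
By default all paired-associates encoding epochs enter (both
distractor-task conditions and immediate recall - the planted pattern is
the same); `encoding_scope = "distractor_only"` restricts to the
distractor-task conditions.

## Group inference

Per ROI, subject d' values are tested with a one-tailed Wilcoxon
signed-rank test against zero, and cross-decoding proportions against the
50% chance level. The test drops zero differences (classical convention,
rather than Pratt's), uses midranks for ties, enumerates all `2^n` sign
assignments exactly for `n <= 12`, and otherwise applies the normal
approximation with tie and continuity corrections; the
normal-approximation Z is reported in both regimes for comparability.
Only ROIs whose d' test clears the gating level (`alpha = 0.05`) enter the
reactivation analysis - the second analysis is conditional on the first
having found local information. No correction is applied across ROIs; the
report metadata records this.

Behavioural comparisons are two-tailed paired t-tests: probe recall
(distractor-condition mean of two blocks vs immediate recall), vocabulary
accuracy, and vocabulary reaction time, reported with condition means, SDs
and the 16/3 = 5.33-pair probe chance level.

The temporal-proximity control asks whether encoding volumes are
increasingly classified as distractor-condition toward the end of the
encoding period, as a proximity/context account would predict. Two modes
are computed, because they answer slightly different questions and carry
different degrees of freedom: a pooled mode (Pearson r between the
across-subject proportion and the volume number; dof = volumes - 2) and a
per-subject mode (each subject's own correlation, Fisher-z transformed,
one-sample t across subjects; dof = subjects - 1). Both are reported; a
saturated (constant) series is recorded as not testable rather than an
error.

## Problem sizes used in validation

The packaged checks run, by design, at desk scale: null calibration uses
200 replicate cohorts of 12 subjects on the default 24 x 24 x 16 grid with
decoding restricted to the pattern sphere (statistically identical to
extracting the sphere from the full volume, since noise is voxelwise
independent); power uses 100 cohorts of 35 subjects at rho = 0.6 with
pattern amplitude equal to the noise SD; localizer recovery uses 20 cohorts
of 10 subjects at cluster amplitude 5x the noise SD, requiring every
planted peak within one voxel (Chebyshev distance). These sizes were chosen
once as the smallest that make the calibration bands meaningful.

## What passing these checks does and does not show

The generator emulates the block structure, counterbalance orders, HRF
dynamics, and planted univariate and multivariate signals of the paradigm,
with independent Gaussian (optionally AR(1)) noise. It does not emulate
physiological noise structure, motion-correlated artifacts, susceptibility
dropout, between-voxel noise correlations, trial-wise item variability
within blocks, or between-subject anatomical variability. Consequently,
passing calibration here validates the *pipeline* - extraction windows,
centering algebra, fold bookkeeping, classifier orientation, test
calibration - not the claim that real cortical reactivation would be
detectable at any particular strength. Effect sizes on real data depend on
signal components (for instance volume-to-volume fluctuation of
reactivation) that this forward model intentionally leaves out.

## Known limitations

* Bonferroni FWE is conservative relative to random-field methods; on
  smooth real data it would cost sensitivity.
* The baseline-referenced cross-decoding threshold assumes the ROI's
  spatial-mean-removed baseline is a meaningful origin; strong sustained
  univariate activation inside the ROI widens the per-subject spread of
  the proportion (symmetrically), reducing power.
* Cluster peaks are reported in voxel indices of the simulated grid; no
  template-space coordinates exist for synthetic data.
* The Wilcoxon exact path is O(2^n) and switches to the corrected normal
  approximation above n = 12.
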