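---
title: "Developing and evaluating pain-empathy pattern signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing and evaluating pain-empathy pattern signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painsig)
```

## The problem and the model

Multivariate pattern analysis treats a whole-brain activation image as a
single observation $x \in \mathbb{R}^V$ over the in-mask voxels, and a
"neural signature" as a linear decoder $f(x) = w^\top x + b$ whose scalar
output (the *pattern response*) separates experimental conditions.
`painsig` implements the full development-and-evaluation cycle for such
signatures in the setting of pain empathy evoked by social stimuli: four
control-subtracted conditions per subject (exclusion, inclusion, separation,
company: Ex, Inc, Sep, Com), one-vs-all and pairwise linear SVM decoders
(C-classification, $C = 1$, no feature scaling), forced-choice evaluation
under repeated subject-fold cross-validation, bootstrap/Haufe "core system"
identification, atlas-based cosine decomposition, rating-stratified
decoding, and multilevel two-path mediation between signature responses and
trial ratings.

The SVM is fit on raw contrast values by a standard convergent solver for
the hinge-loss/$C$ objective (libsvm via `e1071`); a hard-margin analytic
solution on a two-point toy serves as its oracle in the test suite. Nothing
downstream depends on the particular optimizer.

## First-level GLM

`build_design()` convolves condition boxcars with the canonical double-gamma
HRF (peak 6 s, undershoot 16 s, peak:undershoot ratio 6, unit rate), adds a
24-column motion block per run (6 parameters, squares, first differences,
squared differences), a discrete-cosine high-pass basis with a 128 s cutoff,
and a run intercept; runs are concatenated with run-specific nuisance
blocks. Estimation in `fit_glm()` is voxelwise OLS without prewhitening — a
deliberate simplification: autoregressive noise modelling changes standard
errors we never use (all downstream inference is resampling-based), not the
beta point estimates the signatures consume. Three design variants cover
condition betas, rating-parametric modulators, and simultaneous single-trial
regressors (one design with all trial columns, not iterative
leave-one-trial-out, for determinism and speed).

Two choices that the field leaves open are fixed here and flagged to users:
the parametric rating modulator is mean-centered but **not** orthogonalized
against its condition boxcar, and initial dummy volumes are dropped
symmetrically from data and design via `drop_initial` (5 at the reference
settings).

## The synthetic cohort

All statistical claims in the package are exercised on a generator with
known ground truth (`synthetic_truth()`), emulating the study structure the
pipeline assumes: 65 subjects x 4 control-subtracted conditions, 60 single
trials per task condition, 1-5 ratings, a 24-ROI / 7-network parcellation.

* **Patterns.** Condition patterns are
  $p_c = \rho\, g + \sqrt{1-\rho^2}\, u_c$ with $g, u_c$ orthonormal
  Gaussian draws, so every pairwise pattern cosine is exactly $\rho^2$
  (default $\rho = 0.5$). A mediator pattern with stated cosine overlap
  (default 0.5) to the exclusion pattern supports the mediation tests.
* **Amplitudes.** Pain conditions (Ex, Sep) have mean amplitude 1 per
  subject (SD 0.2); their matched controls have mean 0 — control
  subtraction is assumed already done.
* **Noise.** Voxelwise i.i.d. Gaussian. Because discrimination depends on
  the *image-level* noise norm $\sigma\sqrt{V}$, "high SNR" in the tests
  means $\sigma$ small enough that this norm sits below the unit signal
  norm (0.02 at the 10^3-grid's ~280 voxels); recovery ladders use
  $\sigma \in \{1, 0.1, 0.02\}$.
* **Ratings.** A latent Gaussian — intercept + slope x trial expression +
  noise — rounded and clipped to 1..5. The defaults (slope 1.5, latent
  noise 1.25) reproduce the heavy rating-1 skew of the emulated study's
  trial counts (roughly 52/22/13/9/4% across levels 1-5).
* **Reproducibility.** One global seed fans out to arithmetic per-subject
  substreams, so any subject subset regenerates identically.
* **What it does not emulate:** spatial autocorrelation, physiological
  noise, inter-subject anatomical variability (a pattern-jitter parameter
  exists but defaults to 0 rather than guessing an undocumented value), or
  hemodynamic nonlinearity. Passing tests therefore certify the
  *estimators*, not performance on real data.

## Evaluation choices

* **Cross-validation folds partition subjects**, never images: a subject's
  images are dependent, and image-level folding would leak. This is the
  conservative reading of an ambiguous full-scale procedure, exposed as the
  only behaviour.
* **Forced choice**: within each subject the condition image with the larger
  pattern response is predicted; exact ties earn 0.5 credit and are
  excluded from the (exact, two-sided binomial) chance test — unbiased
  under the null. Accuracy is invariant to positive weight rescaling and to
  the intercept.
* **AUC** is reported as the single-interval (Mann-Whitney) area over the
  pooled responses rather than the paired proportion; the two can differ,
  and published companion metrics are only consistent with the
  single-interval reading.
* **Effect size** is the mean over SD of the paired response differences.
* One-vs-all decoders can score *below* chance on pairs of their negative
  conditions (e.g. Sep vs Com under a decoder trained to reject both): the
  margin objective actively suppresses the shared-signal direction. This is
  expected behaviour, visible in `analysis/04_evaluate.R`.

## Core systems

Step 1 (`bootstrap_weights()`) resamples **subjects** with replacement
(images travel with their subject), retrains the SVM per sample, and forms
voxelwise $z = \text{mean}/\text{SD}$ over the bootstrap distribution with
normal-theory two-tailed p-values — matching the described full-scale
procedure — rather than percentile p-values; degenerate voxels (zero
bootstrap SD) get $z = 0$, $p = 1$. Step 2 (`haufe_encode()`) converts the
backward model into forward-model structure coefficients
$A = \Sigma_x w$ using each subject's sample covariance of its condition
images (the observation unit is ambiguous at full scale; condition images
are the default and single trials are supported via the `conditions`
argument, with a pooled `unit = "group"` variant behind a flag), followed
by a group one-sample t-test. Both maps are thresholded by
Benjamini-Hochberg FDR at $q = 0.05$ and intersected
(`conjunction_core()`). The core map is strictly an interpretation product:
classification always uses the full weight vector.

A calibration subtlety: voxelwise bootstrap z-values within one dataset are
correlated through the shared resamples, so their empirical mean and SD
wobble appreciably dataset-to-dataset even under the null. The test suite
therefore pools z-values over five independent null cohorts before
asserting the ~N(0,1) band.

## Spatial similarity

`regional_cosine()` rectifies the map (all voxels kept positive for
interpretation) and computes, per region, the cosine between the restricted
map and the region indicator — the map's concentration in the region;
ribbons are normalized to the maximum cosine across regions.
`contribution_shares()` operationalizes "relative contribution" as the
voxel-winner share: each voxel goes to the map with the highest rectified
value (ties split equally), and shares sum to 100% per region. A
cosine-ratio alternative is available via `mode = "cosine_ratio"`. Regions
with no voxels, or all-zero in every map, are reported missing, never 0.

## Rating-stratified decoding

`stratified_forced_choice()` averages each subject's same-rating trials per
condition — a stated approximation of rating-parametric betas — and runs
forced choice per level (fixed decoder) or repeated CV (retrained). Two
generator regimes probe the logic that matched-rating comparisons are meant
to expose:

* `signal_mode = "amplitude"`: the condition-specific pattern scales with
  the rated expression, so accuracy climbs with rating level;
* `signal_mode = "additive"`: a constant condition-specific component rides
  on a rated shared component, so the profile is flat.

Two statistical facts shaped the test regime. Under the default heavy
rating-1 skew, per-level trial counts fall so fast that the amplitude
regime's signal gain ($\propto$ expression) is cancelled by the
$1/\sqrt{n_r}$ averaging noise — the gradient is provably non-monotone — so
the stratified analyses use a balanced rating link (slope 3, latent noise
0.3). And a *flat* profile with continuous estimation noise makes the
Spearman correlation over five levels permutation-uniform, so flatness is
only demonstrable where the profile is pinned (at ceiling): the additive
regime uses a condition component well above noise (`additive_scale = 4`),
where the profile is constant and the correlation exactly zero.

## Mediation

`mediate()` fits per-subject OLS paths ($a$: X to M; $b, c'$: Y on X and M;
$c$: Y on X; the identity $c = c' + ab$ holds exactly per subject) and
draws group inference by bootstrapping subjects: percentile CIs and
two-tailed bootstrap p-values on the across-subject means, with the
indirect effect summarized as the mean of per-subject $a_i b_i$. This
summary-statistics approach (rather than a full mixed-effects likelihood)
matches the bootstrap test of the emulated procedure and keeps the contract
desk-testable; the percentile (not BCa) CI and the desk default of 2000
resamples (configurable to 10000) are recorded choices. Predictor and
mediator are z-scored within subject by default (ratings stay raw); a flag
disables it. Mediation requires $a$, $b$ and $ab$ all significant; it is
"partial" if $c'$ survives, "complete" otherwise. `signature_mediation()`
derives X and M as pattern responses on single-trial images and reports
both directions. The mediator is only identifiable at moderate response
noise: too little and the two signature responses are collinear proxies of
the trial expression (a guarded error), too much and the indirect path
vanishes.

## Problem sizes and determinism

The reference desk configuration (`default_config()`) — 16^3 grid
(~1500 in-mask voxels), 20 subjects, 200 bootstrap samples, 20 CV repeats —
runs the whole pipeline in about a minute on one CPU and is byte-identical
across reruns with equal seeds; all randomness flows from explicit seeds
through deterministic substreams. The analysis drivers under `analysis/`
scale the cohort to 65 subjects and state their regimes inline; heavier
full-scale settings (10 x 10-fold with 1000 repeats, 10000 bootstrap
samples) are plain configuration changes.

## Known limitations

Real-data performance claims are out of reach of the synthetic cohort by
design. The GLM omits prewhitening and slice-timing/motion preprocessing
(inputs are assumed preprocessed). Nearest-neighbour resampling of external
weight maps is intentionally simple — signatures are resolution-robust dot
products — and no cluster-extent or TFCE correction is offered for the
voxelwise maps.
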