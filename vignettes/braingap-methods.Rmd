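---
title: "Brain-based BMI-gap modelling: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-based BMI-gap modelling: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Body-mass index (BMI) leaves a reproducible imprint on brain structure:
higher BMI is associated with lower grey matter volume (GMV) in frontal,
temporal, insular and cerebellar cortex.  A supervised model trained to
predict BMI from voxel-wise GMV in healthy controls therefore defines a
normative brain-BMI relationship, and the signed residual of that model on a
new person — the **BMI gap**, brain-predicted minus measured BMI — reads as
"this brain looks like that of a heavier (or lighter) person than the scales
say".  In early psychiatric populations (schizophrenia, clinical high-risk
states, recent-onset depression) the gap is a candidate marker for metabolic
risk stratification: a positive gap means the brain already carries
higher-BMI-like alterations and may flag susceptibility to future weight
gain.

`braingap` implements that whole analysis chain as reusable, tested
components: a phantom-cohort generator with known ground truth, discovery
cohort construction, a leakage-safe preprocessing chain, a repeated
nested-cross-validation engine for linear support-vector regression (BMI)
and classification (diagnosis), the bias-corrected gap itself, voxel-level
model interpretation maps, sparse partial least squares (SPLS) for
clinical-anatomical covariance, and the longitudinal weight-gain analyses.

# The phantom generator

Real voxel-wise GMV cohorts of the necessary size are not shippable, so
every stage is exercised on phantoms whose generative truth is known and
recorded.  The generator emulates, deliberately coarsely:

* a 3-D voxel grid (default 12 x 12 x 12 = 1728 voxels) carved into
  contiguous regions, with a spatially contiguous, predominantly negative
  (80%) **BMI signature** of 60 voxels and a **disease signature** of 60
  voxels sharing 50% of its voxels with the BMI signature;
* demographics: ages uniform on 15-75, BMI truncated-normal
  (mean 24.5, SD 3.5 kg/m^2) on 18.5-35 kg/m^2 with an age-BMI correlation
  of 0.25 (a "natural correlation" whose exact size is rarely reported;
  0.25 is a mid-range literature value);
* nuisance structure: per-voxel linear age slopes (mean -0.002 units/year),
  a small additive sex pattern, and scalar per-site offsets (4 sites,
  SD 0.05) on a baseline GMV of 0.5;
* a per-subject latent **gap propensity** (kg/m^2 scale, SD 1.5) entering
  the voxel pattern through the same slope as measured BMI but drawn
  independently of it, plus per-group mean shifts
  (SCZ +1.0, CHR +0.5, ROD -0.8 kg/m^2) — this is the ground truth that a
  corrected gap should recover;
* a clinical latent severity factor in patients, loading on PANSS total,
  age of onset, illness duration and hospitalizations, and expressed in the
  brain as a signed template on the overlap voxels;
* follow-up weights whose 1- and 2-year changes couple to the gap propensity
  (1.5 kg per kg/m^2 at two years versus 0.8 at one year, residual SD 3 kg,
  drifts +1/+2 kg, missingness 20%/35%).

Voxel noise is iid Gaussian (SD 0.15).  Effect sizes are not reported for
real voxel-BMI associations at this granularity, so the defaults were fixed
once, at design time, to make the seeded structure recoverable at a few
hundred subjects (per-voxel BMI correlation ~ 0.4, per-voxel clinical-latent
correlation ~ 0.3); they are conditions for testability, not claims about
effect sizes in real data.  What the phantoms do **not** emulate: spatially
correlated noise, segmentation artifacts, scanner physics, non-linear age
effects, or realistic regional anatomy.  Passing tests on phantoms therefore
demonstrates correctness of the machinery and recoverability under the
stated model — not performance on real MRI.

Two generator choices deviate from the most literal reading of the intended
data model and deserve a note:

* the gap propensity multiplies `beta_bmi` together with the BMI deviation,
  so that one propensity unit produces exactly one kg/m^2 of brain-predicted
  shift regardless of `beta_bmi`; this is what makes "group offsets are
  recovered in corrected gaps" a well-posed parameter-recovery test;
* the clinical-latent voxel pattern is a signed (+-1) template on the
  overlap voxels (BMI-signature sign with every second voxel flipped) rather
  than a uniform addition.  A uniform addition lies along the BMI-predictive
  direction, so any detectable loading leaks clinical severity into
  predicted BMI and corrupts the gap; the signed template is orthogonal to
  that direction while remaining a perfectly recoverable SPLS pattern.

# Discovery cohort construction

Healthy controls aged 15-75 with BMI in [18.5, 35] (closed bounds; missing
values excluded with a logged reason) are sorted into 33 half-open BMI bins
of 0.5 kg/m^2 (the last bin closed).  The discovery sample approximates a
uniform BMI distribution: per-bin quotas as equal as supply allows, with
shortfalls moved to neighbouring bins; within each bin the quota is filled
by greedy quantile matching of age against the pooled age distribution,
which both flattens the BMI histogram and curbs the age-BMI correlation.
Everyone not selected forms the validation sample.  Matching is
deterministic given the seed; only membership, never data, is changed.

# The preprocessing chain

Fitted strictly on training data, applied frozen:

1. **Gaussian smoothing** (FWHM 2 voxels ~ 6 mm at 3 mm voxels; kernel mass
   renormalized within the grid/mask).  Smoothing has no fitted parameters
   and acts on one subject at a time, so the training engine applies it once
   to the whole matrix before the cross-validation loop; ensembles record
   the kernel and re-apply it to new data.
2. **Age residualization**: per-voxel ordinary-least-squares slope on
   training age; the residual keeps the training voxel mean so predictions
   stay on the GMV scale.  Only the voxels are residualized; the BMI label
   is left raw.
3. **Site correction**: one scalar per site — the site's mean global GMV
   minus the training grand mean — subtracted from every voxel.  Sites
   unseen at training time get an offset from their own application-sample
   mean (flagged), which is what allows transfer to new cohorts.  This is a
   global-mean offset correction, not per-voxel harmonization.
4. **PCA**, retaining components up to 80% cumulative variance by default
   (1.0 makes the chain an exact rotation and round-trips to machine
   precision).
5. **Min-max scaling** of each component to [0, 1] with training bounds;
   out-of-range values on application are clipped.

Model weights in component space pull back exactly to voxel space through
scaling and PCA (`w_voxel = P (w / (max - min))`); age and site steps mix no
voxels.  A degenerate (zero-width) scaling range contributes nothing and is
flagged.  For low-dimensional tabular models the chain reduces to in-fold
median imputation plus z-scoring.

# Nested cross-validation and significance

The engine runs 5 outer folds x 5 repetitions; hyperparameters (cost grid
`2^(-6..4)`, and for regression epsilon at `{0.05, 0.1, 0.2}` x label SD)
are selected in inner CV (5 folds, up to 5 repetitions) run strictly inside
each outer-training partition, minimizing inner out-of-fold MAE (regression)
or maximizing balanced accuracy (classification); ties go to the smaller
cost.  The winner is refit on the full outer-training partition
(winner-takes-all rather than inner-model averaging).  Per-subject
out-of-fold predictions are averaged across repetitions; classifier decision
scores averaged the same way are the "disease expression" scores.  Class
imbalance is handled by inverse-frequency class weights in the SVC loss.
Model significance uses label permutations with the fold assignment fixed:
the full nested pipeline is re-run per permutation and
`p = (1 + #{as good}) / (1 + n_perm)`.

The gap bias correction is an OLS fit of the raw gap on measured BMI in the
discovery cohort's out-of-fold predictions — the only predictions that are
simultaneously unbiased and in-cohort — and is then transferred frozen to
every other cohort.  Regression to the mean guarantees the familiar
over-/under-estimation bias (negative slope); by OLS orthogonality the
corrected gap has exactly zero mean and zero BMI correlation in the fitting
cohort, and deliberately not elsewhere: re-fitting on a target cohort would
erase the very group shifts the gap is supposed to measure.

# Interpretation maps, and a caveat that matters

Per voxel across the 25 ensemble members we report the cross-validation
ratio (mean weight / SE of the mean; zero-SE voxels get a signed cap) and
sign-based consistency (majority sign fraction, exact zeros excluded; exact
two-sided binomial test against 0.5; Benjamini-Hochberg q across voxels;
binarization at q <= 0.05 by default).  Overlap of two binarized maps is a
plain logical AND, sign-agnostic, with per-voxel sign concordance reported.

The binomial test treats members as independent.  They are not: any two
outer members share roughly three quarters of their training subjects, so
the noise-driven part of a voxel's weight is nearly identical across members
and its sign is far more stable than a fair coin.  Measured on phantoms with
*no* seeded signal at all, over half the voxels reach q <= 0.05.
Sign-consistency maps over CV ensembles are therefore a **selection and
visualization heuristic**, not calibrated voxel-level inference: recovery of
true signal is excellent (>= 90% of seeded voxels at default SNR), but the
voxel-level false-positive rate is far above q and no generator setting
changes that, because the dependence is a property of the resampling
geometry, not of the data.  The binomial/BH machinery itself is calibrated —
the test suite verifies this with independent synthetic members — and
model-level permutation tests are exact and unaffected.  Conclusions should
be drawn from map peaks and overlaps descriptively, with model-level
significance coming from the permutation tests.

# Sparse partial least squares

The clinical block (six standardized features: BMI gap, disease-expression
score, PANSS total, age of onset, illness duration, hospitalizations) and
the overlap-voxel block are coupled through penalized rank-1 decompositions
of the cross-covariance `M = X'Y`: alternating soft-thresholded updates with
the L1 bound enforced by bisection, unit L2 norms, initialization at the
dense singular pair, and the sign convention that the largest clinical
weight is positive.  With the constraints released the fixed point is the
leading singular-vector pair of `M` (verified to cosine > 0.999 on random
problems).  Successive latent variables are obtained by projection deflation
(removing the fitted scores from their own blocks — stabler under sparsity
than deflating `M` itself), gated by a permutation test that permutes the
rows of one block only, and bounded by `max_lv`.  Sparsity can be selected
per latent variable by k-fold cross-validated out-of-fold score correlation
with ties to the sparser setting; this matters in practice, because dense
rank-1 fits on a few hundred voxels against ~150 subjects overfit so
strongly that the permutation null reaches the observed correlation.  Weight
stability comes from a case-resampling bootstrap with sign alignment to the
original fit.  Standardization uses the analysis sample's own mean and SD —
the SPLS is descriptive, not predictive, so there is no train/test split
inside it.

# Weight-gain analyses

Weight changes are `dW = W_follow-up - W_baseline` with percentage changes
relative to baseline; thresholds (>= 3/5/7%, inclusive) and age windows
(lower-bounded and 5-year bins), sex and group filters define the
correlation-scan cells (cells under 5 subjects report no correlation).  The
scan uses the corrected gap throughout.  Individual-level prediction of
threshold weight gain uses the same nested-CV engine on the tabular features
(gap, age, sex, group dummies, exercise, somatic history, optionally
tobacco), with in-fold imputation and standardization only.  The with/without-gap
comparison is a paired sign-flip permutation test on per-subject out-of-fold
correctness differences under a shared CV assignment — exact under
exchangeability of the paired differences.

# Numerical and engineering choices

* Determinism: every stochastic step takes an explicit seed; substream seeds
  are derived from a master seed so stages are independently reproducible,
  and identical configurations produce byte-identical artifacts.
* Smoothing operators are sparse banded Kronecker products, cached per
  (grid, FWHM, mask).
* PCA uses the SVD of the centred training matrix; components below a
  numerical rank tolerance are dropped.
* Degenerate cases are contracts, not crashes: single-class training
  partitions mark a member degenerate (the run fails above 20% degenerate
  members); zero-variance voxels get zero age slopes; empty scan cells
  report missing correlations.
* The problem sizes used by the shipped tests and the acceptance script —
  1728 voxels, 400 discovery controls, clinical groups of 146/213/200, a
  3-point cost grid with 5x1 inner CV, permutation counts of 99-2000 —
  were chosen so the whole suite completes in minutes on one core while
  keeping every recovery property measurable; the engine itself scales to
  the full grids and grids of costs via configuration.

# Known limitations

* Sign-consistency voxel inference is anti-conservative over CV ensembles
  (see above); treat binarized masks as descriptive.
* The site model is a scalar offset; multiplicative or voxel-wise site
  effects (ComBat-style harmonization) are out of scope.
* The phantom's iid noise makes mass-univariate recovery easier than on real
  data with spatially correlated noise.
* Group gap means in phantoms that seed both a propensity shift and an
  overlapping disease signature recover the *sum* of both influences — the
  disease pattern itself pushes predicted BMI, which is the substantive
  point of overlap analyses, but it means seeded propensity offsets are only
  cleanly identified with the disease effect switched off.
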