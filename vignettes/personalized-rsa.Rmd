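---
title: "Personalized-model RSA and identity decoding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized-model RSA and identity decoding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When different people imagine the same everyday scenario — a wedding, a
drive, housework — they draw on different memories, so the neural
representation of "a wedding" should carry a personal signature on top of
what everyone shares.  `rsaid` implements a pipeline that makes this
question quantitative: personal models of each participant's imagined
scenarios are built from two behavioral channels (free verbal descriptions
and Likert ratings of experiential attributes), brain and models are
compared in representational similarity space, population-common structure
is controlled away with leave-one-out group-average models, and finally
participant identity is decoded by asking whether each person's own model
fits their own brain data better than someone else's.

## The representational similarity machinery

Every data source — an S x V matrix of scenario voxel patterns, an S x A
attribute-rating matrix, an S x D matrix of composed verbal vectors — is
re-represented the same way: the Pearson correlation between every pair of
scenario rows is computed over the feature dimension, Fisher z (arctanh)
transformed, and the below-diagonal triangle of the S x S matrix is
vectorized.  With S = 20 scenarios this gives a 190-entry similarity
vector.  The traversal is R's column-major `lower.tri()` order; any fixed
order would do, since every comparison happens between vectors sharing it,
but the order is documented (and recorded in the TSV exports) so that
vectors exported from other tools can be aligned.  Correlations are clipped
to ±(1 − 1e−7) before arctanh so duplicated patterns stay finite.

Model-to-brain comparison uses Spearman correlation (average ranks on
ties).  The multimodal personal model is the pointwise sum of the z-scored
verbal and attribute similarity vectors; summing rather than averaging
changes only a constant factor, to which rank correlation is insensitive.
The G-1 group-average model for participant p is the pointwise mean of the
other participants' model similarity vectors (a feature-space averaging
variant — average the model matrices first, then correlate — is available
through `group_average_loo(space = "feature")`).

Two permutation schemes give single-participant p-values:

* **Plain RSA**: scenario order is shuffled, rows and columns of the fMRI
  correlation matrix (only) are rearranged accordingly, and the shuffled
  triangle is re-correlated with the model; p is the fraction of 1000 null
  coefficients at or above the observed one.
* **Partial RSA**: because shuffling the brain vector would also break its
  relation to the *control*, the null must preserve the group component.
  All three vectors are ranked; the ranked brain vector is regressed on the
  ranked G-1 vector (with intercept); the residuals are put back into
  their triangle positions and row/column-shuffled at the scenario level;
  the fitted group component is added back; and the partial correlation
  with the ranked personal model (controlling the ranked G-1) is
  recomputed.  With the identity shuffle this reconstruction reproduces
  the ranked brain vector exactly — a property the test suite asserts to
  1e−10.  Including the intercept in the add-back is an interpretation
  choice; since the partial correlation is invariant to any affine
  function of the control, it does not affect the statistic.

Both p-values use the plain fraction of null statistics greater than or
equal to the observed one, so p = 0 is attainable; an optional
`estimator = "add_one"` switches to the (b+1)/(B+1) estimator for users
who need strictly positive p-values.

## Voxel preparation

Within each run, every voxel time course and every nuisance regressor (six
motion parameters plus a linear trend) is z-scored (population SD) and the
voxel is residualized by ordinary least squares.  A constant nuisance
column carries no information after z-scoring and is dropped; a duplicated
column is a genuine error.  Scenario responses are then formed by averaging
the residual volumes in a window (5, 15] s after onset — at TR 2.5 s the
four volumes at offsets +2...+5, under the convention that volume j covers
[j·TR, (j+1)·TR).  Averaging, rather than convolving a canonical
hemodynamic response, deliberately avoids assuming a common response
latency and duration across participants, which is exactly the kind of
interpersonal difference the pipeline is trying to measure.

Voxel selection uses inter-run stability: for each voxel, the Pearson
correlation of its S-scenario profile between every pair of runs (10
coefficients for 5 runs), arctanh-transformed and averaged.  The 100 most
stable voxels per anatomical ROI are kept (all of them when the ROI is
smaller), ties broken by ascending voxel index for determinism.  A voxel
with zero variance within a run contributes 0 for the affected pairs by
default (`undefined = "drop"` removes those pairs from the mean instead).
Finally, replicates are averaged per scenario and each voxel is z-scored
across scenarios.

## Group inference

Per-ROI inference is a one-tailed (greater) one-sample t-test across
participants on arctanh-transformed coefficients, with Cohen's d reported
as t/√n and Benjamini–Hochberg FDR across ROIs (Benjamini–Yekutieli
available for dependence-robust correction).  ROIs can be selected either
against the G-1 models or, for a given target participant, from the other
participants' personal-model fits only — the target's own data never
touches their selection.  The count of individually significant
participants in a region is summarized with the upper-tail binomial
probability; for 26 participants at the 0.05 level, observing 4 or more is
itself a 0.04 event.

The searchlight analog slides a cube of radius 3 voxels (side 7) over the
common mask, computes the chosen RSA within each in-mask cube, assigns the
Fisher-z coefficient to the center, and corrects each map separately by
FDR.  Following the ROI logic, the partial-RSA map is restricted to
centers where the group-average map survived correction (an unrestricted
mode exists for exploration).  Cubes with fewer than 10 in-mask voxels are
skipped; the threshold is exposed because edge intersections otherwise
produce unstable correlations.  Inference uses q = 0.05; a more lenient
display threshold (q = 0.1) can be passed where map visibility matters.

## Identity decoding

For a pair of participants, the four Spearman correlations between the two
personal models and the two brain similarity vectors are arctanh
transformed; the pair is decoded correctly when the congruent sum
(own-model-to-own-brain, both participants) beats the incongruent sum.
Accuracy is the percentage of correct pairs over all P(P−1)/2 unordered
pairs (325 for 26 participants), with 50% expected under no
participant-specific association.  Exact ties score 0 under the
conservative default (`ties = "half"` awards half credit).  Significance
comes from 10,000 random reassignments of the brain vectors to
participants — full permutations, fixed points allowed.  The
implementation precomputes the P x P cross-correlation matrix once, so the
permutation loop is arithmetic only.  A model-only analog decodes the
verbal channel against the attribute channel, giving a reference accuracy
that needs no imaging data.

## The synthetic cohort generator

The generator exists so that every stage of the pipeline is exercisable —
and its statistical claims testable — without any external data.  Each
participant's scenario latent is a convex mixture

    latent_p = (1 − λ) · group + λ · personal_p

with independent personal components, so the single parameter λ
(`idiosyncrasy`) sets how much identity signal the cohort carries.  All
three channels derive from the same participant latents: voxels through an
ROI-specific linear readout switched on by a delayed boxcar (delay 2
volumes, duration 4 — matching the averaging window), plus
motion-correlated artifact, per-voxel linear drift, and white noise;
ratings through shared attribute directions, affine-mapped to 0–6 and
rounded (clipping at the ends is expected and kept); descriptions as the 8
vocabulary words nearest the latent's projection into a topic-structured
embedding space.  Scenario order is re-randomized per run.  An option
drops the first presentation of run 1 to emulate discarded initial
volumes, leaving one scenario with one fewer replicate.

Defaults mirror the study design they emulate: 26 participants, 20
scenarios, 5 runs, 20 attributes, TR 2.5 s, 3 stimulus + 3 fixation
volumes.  Values the design does not pin down were chosen once, for
realism, and are worth stating explicitly:

* `latent_dim = 30`, deliberately larger than the number of scenarios.
  With a latent rank at or below S, the sampled scenario geometry is
  rank-deficient: similarity values crowd toward extremes, near-ties
  appear, and rank-based partial RSA becomes anticonservative at λ = 0
  because both channels' rank perturbations concentrate on the same
  near-tied entries — something the scenario-level shuffle cannot mimic.
  A full-rank geometry is also the more realistic assumption: there is no
  reason to expect imagined-scenario representations to obey an exact
  low-dimensional constraint.
* `noise_sd = 4` puts the single-pattern voxel SNR near 1, typical of
  event-related pattern analyses; `rating_noise_sd = 1` corresponds to
  roughly one Likert step of rating unreliability.
* λ defaults to 0.5 — an equal split between shared and personal
  structure.  The underlying study gives no quantitative estimate of this
  ratio, so it is an explicit free choice, and the test suite exercises
  λ = 0, 0.5 and 1.

What the generator does *not* emulate: anatomical geometry, physiological
noise spectra, spatial autocorrelation, multi-band artifacts, and the
lexical richness of real descriptions.  Passing tests on synthetic cohorts
therefore demonstrate the statistical correctness of the machinery — null
calibration, signal recovery, determinism — not that real data will show
any particular effect size.

## Numerical choices and degenerate inputs

* Population-SD z-scoring throughout (sample SD available where exposed);
  on a two-point column this maps 0 and 6 to −1 and 1.
* Correlation clipping at ±(1 − 1e−7) before arctanh.
* Constant attribute columns become zeros with a warning (shape
  preservation beats erroring mid-cohort); constant voxels across
  scenarios likewise.
* A personal model rank-identical to its control is rejected as degenerate
  rather than returning a meaningless partial coefficient.
* Stability ties break by voxel index; all permutation tests take explicit
  seeds and are bit-reproducible.

## Known limitations

The partial-RSA permutation test inherits mild significance at λ = 0 when
the G-1 control is estimated from few, noisy peers: regressing on a noisy
control leaves a shared remnant of the group component in both residuals
(an errors-in-variables effect).  At the design's cohort size (25 peers in
every control) the test is calibrated to within sampling error of its
nominal level — the acceptance suite measures this — but users running the
pipeline on small cohorts with unreliable behavioral channels should
expect the individual-level partial p-values to be slightly liberal.  The
group-level t-tests across participants do not depend on the permutation
machinery and are unaffected.

Problem sizes in the test suite and analysis scripts (cohorts of 6–26
participants, grids up to 6 x 6 x 16, 150–1000 permutations per test, 200
seeded replicates for null calibration) were chosen so that each claim is
measured with enough replication to be stable while the whole suite stays
comfortably rerunnable on a laptop.
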