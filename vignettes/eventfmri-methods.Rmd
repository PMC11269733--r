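---
title: "Models and methods behind eventfmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind eventfmri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eventfmri)
```

`eventfmri` implements the full analysis chain of a rapid event-related
video fMRI experiment: schedule construction, BOLD simulation with known
ground truth, trial-wise FIR deconvolution, split-half reliability,
probabilistic-map ROI definition, searchlight representational similarity
analysis (RSA) with noise ceilings, voxelwise feature encoding, variance
partitioning of within-video temporal epochs, and memorability-response
correlation. This vignette explains the models, the parameters that
matter, and the design decisions taken where the methods literature leaves
choices open.

## The experimental design

The canonical experiment presents 1000 training videos three times each
and 102 testing videos ten times each, spread over 4 scanning sessions of
13 runs (3 testing, 10 training). Every trial is 4 s: a 3 s video plus
1 s of fixation, or 4 s of gray screen on null trials. A testing run has
85 stimulus and 28 null trials (113 total), a training run 75 and 25
(100 total); with a 4 s lead-in and 13 s / 12.5 s lead-out at an
acquisition TR of 1.75 s this gives exactly 268 and 238 volumes. The
functional localizer uses 25 blocks of 18 s plus 19 s of trailing gray
screen, again 268 volumes.

`build_session_schedule()` enforces the structural constraints rather
than assuming them: training videos never repeat within a session
(realised by assigning each video a balanced cyclic window of sessions),
no video appears on consecutive stimulus trials, and no two testing runs
are adjacent. Null trials are placed per run at exactly `round(n_stim/3)`
positions - the experiment states a 25% proportion without saying whether
it is enforced per run or per session; per-run enforcement is the stricter
reading and makes every run's volume count deterministic. Adjacency
constraints are satisfied by rejection sampling with a 10,000-attempt
bound: the acceptance probability is high for all realistic
configurations, and a bounded retry keeps schedules reproducible functions
of the seed. Volume counts use ceiling division; the canonical parameter
sets divide exactly.

## The synthetic-data generator

The generator exists so that every downstream stage has a recoverable
target. Its signal model: each video carries two latent feature vectors
(one for its first second, one for its third), shared between training and
testing sets through a common voxels-by-features weight map supported on a
`reliable_frac` subset of voxels. A trial adds a double-gamma response at
the trial onset for first-epoch content and at onset + `epoch_lag_s`
(default 2 s) for third-epoch content. The HRF is the familiar
double-gamma shape (positive lobe peaking at 5 s, undershoot at 15 s,
peak-to-undershoot ratio 6, normalised to max 1); nothing in the modeled
experiment pins these values, so the conventional shape is used.

Each epoch's amplitude at a voxel is `baseline + latent . w`, scaled by
`(1 + memorability_effect * score)`. The baseline term (default 1, in
response-amplitude units, at signal voxels) represents the positive evoked
response that any visual stimulus produces; it matters because a purely
multiplicative memorability modulation of a zero-mean pattern would leave
response magnitude uncorrelated with memorability, making the
memorability analysis untestable by construction.

Noise has three components, all seeded: AR(1) measurement noise
(innovation SD `noise_sd`, coefficient `ar1_phi`, default 0.4),
trial-level amplitude jitter shared across the delays of one presentation
(`trial_noise_sd`), and a slow drift built from three cosines on the
discrete-cosine-transform phase convention with frequencies below
1/128 Hz, so the GLM high-pass spans the drift exactly by construction.

The default noise level was calibrated once, before any recovery analyses
were run, to place the mean Spearman-Brown split-half reliability of
signal voxels near 0.45 - the middle of the 0.3-0.6 range typical of
single-voxel responses to brief naturalistic stimuli. That calibration
gave `signal_sd = 1, noise_sd = 3, trial_noise_sd = 1.5` and was not
revisited afterwards.

The generator emulates trial timing, repetition structure, epoch lags,
annotation noise on metadata embeddings, and memorability-modulated
amplitudes. It does not emulate anatomical geometry, spatially structured
physiological noise, motion, or susceptibility distortion - so passing
recovery tests demonstrate the estimators' correctness and calibration
under the stated signal model, not robustness to those artifacts.

`simulate_beta_tensor()` draws trial-wise FIR amplitudes directly from
the same generative model, skipping time-series simulation. Downstream
analyses are validated against it at sizes where full GLM estimation
would dominate runtime; the GLM itself is validated separately (below).

## FIR modeling and its identifiability limit

The GLM stage resamples each voxel's time series from the 1.75 s
acquisition grid to a regular 1 s grid by cubic interpolation (exact on
polynomials up to cubic, accurate to about 1e-3 on band-limited signals),
then estimates one free response value per (trial, delay) pair at delays
1..9 s after onset. Null trials are unmodeled. A discrete-cosine set with
a 128 s period cutoff is projected out of data and design; with `ar1`
enabled, a single AR(1) coefficient pooled across voxels within the run
is estimated from OLS residuals and used to prewhiten before refitting
(the voxel-wise versus pooled scope is a free choice; pooling is the
stabler small-sample option and is what the classical packages do).

Trial-wise FIR with 1 s delay bins has a hard identifiability limit: each
(trial, delay) regressor is a single unit spike, so two trials whose
onsets differ by 8 s or less place spikes on shared volumes and their
columns are exactly collinear. At the canonical 4 s trial spacing the
design is therefore rank-deficient and `fit_fir_glm()` refuses to fit it
rather than silently returning a minimum-norm solution that mixes
neighbouring trials' responses. Noiseless end-to-end validation uses
schedules with 12 s trial spacing (onset differences above the delay
span) and an HRF truncated to the estimation window, under which the
fitted betas reproduce the injected amplitude-by-delay profiles to
machine precision. Beta summaries z-score across stimuli per voxel,
repetition and delay (zero-variance voxels map to 0), average the peak
window (delays 5-9 by default), then optionally average repetitions.

## Split-half reliability

A voxel's reliability is the mean over all 126 unordered complementary
5/5 partitions of the 10 testing-set repetitions of the Spearman-Brown
corrected Pearson correlation between the two 5-repetition averages,
taken across stimuli. Unordered partitions are the right count: the two
orderings of a partition give the same correlation. Negative split
correlations pass through the correction unclipped. The null
distribution permutes the stimulus labels of one split - a fresh
permutation per iteration, applied identically across all 126 partitions
within that iteration, for 100 iterations - and the p-value uses the
add-one form `(#null >= observed + 1) / (n_perm + 1)`, which is valid at
finite permutation counts. Because add-one p-values reach exactly 1,
`select_reliable_voxels()` treats `alpha >= 1` as "no criterion" rather
than excluding those voxels on a strict inequality.

## ROI definition

Per-subject localizer t-maps are thresholded at a Bonferroni
family-wise-error level over in-mask voxels (one-sided, positive tail;
random-field corrections are out of scope and Bonferroni is conservative),
binarised, summed over subjects and divided by the subject count to give
probabilistic maps on the 0.1 grid. A subject's ROI is their surviving
voxels restricted to the map's support and an optional anatomical mask,
capped at the top 1000 voxels by t-value. Overlapping voxels go to the
ROI with the higher map probability; ties grow a cube by one voxel per
dimension (clipped at volume boundaries, mean over in-volume voxels only)
until the tie breaks, with a deterministic first-ROI fallback once the
patch spans the grid. Manual curation of map support is represented by
the anatomical-mask input rather than reimplemented.

## Searchlight RSA and noise ceilings

Searchlight RDMs use a radius-4 sphere (257 lattice voxels), truncated at
volume edges, and 1 - Pearson dissimilarity between stimulus patterns;
centres with degenerate (constant) patterns yield missing RDMs that group
maps exclude. Metadata RDMs average, per video, the 3 most mutually
similar of its 5 annotation embeddings - defined exhaustively as the
triple with maximal mean pairwise cosine similarity over the 10 possible
triples - and use cosine distance between the per-video consensus
vectors; the combined object+scene+action representation concatenates the
three word-level vectors (length 900) before the distance. Model-to-brain
maps use Spearman correlation over the lower triangle, making them
invariant to any strictly monotone transform of the model RDM.

The upper noise ceiling correlates each subject's RDM with the
all-subject average (including that subject) and the lower ceiling with
the leave-one-out average. Including the subject itself is what makes the
upper value an upper bound; a direct consequence, confirmed in the test
suite, is that under fully independent subject RDMs the upper ceiling
does not vanish but sits near `1/sqrt(n_subjects)`, while the
leave-one-out lower ceiling is unbiased at zero. Noise-normalised model
correlations can exceed 1 when a subject beats the ceiling estimate;
values are reported unclipped.

## Encoding models

Features are standardised by training-set statistics, compressed to 100
principal components fit on the training set only (component signs fixed
by making each component's largest-magnitude loading positive, so the
transform is deterministic), and mapped to voxels by per-voxel ordinary
least squares with an intercept. With about a thousand training stimuli
and 100 orthogonal components, regularisation buys nothing and would add
a hyperparameter, so plain OLS is used. Predictions are Pearson-correlated
with each of the 10 held-out repetitions separately and the correlations
averaged - an attenuated but repetition-count-honest score; correlating
against the repetition mean instead gives a higher value except in the
noiseless limit, and both behaviors are covered by tests. Noise
normalisation divides by the voxel's mean split-half correlation before
Spearman-Brown correction, excluding voxels with non-positive split
correlation. Only reliability-selected voxels are evaluated. Shuffled
feature variants are encoded separately and their results averaged
voxelwise before contrasting with the unshuffled result; ROI contrasts
use one-sample two-sided t-tests across subjects with Bonferroni (over
the ROI count) or Benjamini-Hochberg (over an explicit comparison count,
e.g. 88 = 22 ROIs x 4 network blocks) correction.

## Variance partitioning of temporal epochs

Per TR and epoch, a linear regression maps that epoch's features to the
repetition-averaged training betas and predicts the testing stimuli,
giving two synthetic test-response instances. The unique variance of
epoch A at a searchlight centre is
`adjR2(bio ~ A + B) - adjR2(bio ~ B)` with
`adjR2 = 1 - (1 - R2)(n - 1)/(n - p - 1)`, computed with the in-sphere
voxels stacked alongside videos as observations (the regression's
observation set is otherwise underdetermined by the method description;
the stacking choice is documented and the swap-symmetry of the
decomposition is tested). Peak TRs are argmaxes with ties resolved to the
earliest TR - conservative toward smaller peak differences. The
whole-brain test counts subjects whose third-minus-first peak difference
falls in [1, 3] and applies an exact binomial test with a null
probability of 21/81 - the fraction of ordered peak pairs on a 9-TR grid
with difference in [1, 3] under a uniform independence null - followed by
FDR across voxels.

A property of this estimator worth knowing: because R-squared normalises
by total variance, each epoch's unique-variance curve is suppressed at
TRs where the other epoch's response is strong. With a 2 s lag the two
response shapes overlap heavily, which biases the first-epoch peak about
one TR early and the third-epoch peak about one TR late. Under the
calibrated noise level the package therefore recovers an injected 2 s lag
as a modal peak-TR difference of 3 (the acceptance script reports the
honestly computed value); the bias grows with SNR and only vanishes when
noise dominates far beyond the calibrated reliability band. At zero lag
the two curves coincide in expectation and flatten, so per-voxel peak
differences centre on zero but scatter with estimation noise rather than
concentrating exactly at zero.

## Memorability

Memorability follows the linear decay model `m_t = m_T + alpha (t - T)`
with reference lag `T = 80` intervening videos, clipped to [0, 1];
positive decay rates are preserved by default with clipping exposed as an
option. The response correlate pools all videos (training repetitions
averaged over 3, testing over 10; the repetition imbalance is left
uncorrected) and Spearman-correlates scores with per-video amplitudes per
voxel and subject. Group inference is one-sided toward positive
correlation - the stated a-priori direction that memorable stimuli evoke
larger responses - with FDR at q = 0.05 voxelwise and Bonferroni over the
ROI count for ROI means.

## Shared statistics

`bh_fdr()`, `group_ttest()`, `binomial_fraction_test()` and
`anova_tukey()` wrap the standard machinery (`p.adjust`, closed-form t,
`pbinom`, `aov` + `TukeyHSD`) behind one reporting surface. FDR under an
assumed positive dependence uses plain Benjamini-Hochberg (valid under
positive regression dependence; the more conservative variant for
arbitrary dependence is deliberately not used). Comparison counts (22,
88, 18) are always explicit arguments, never inferred. Degenerate inputs
are resolved explicitly: zero-variance t-tests return 0/1 or an infinite
statistic with a flag, constant ANOVA data returns F = 0.

## Problem sizes

The test suite and the acceptance script run at desk scale by choice:
voxel grids of 3^3 to 6^3 (5^3 with a radius-2 searchlight for variance
partitioning), 12-52 videos for most recovery checks, 40 testing stimuli
for reliability sensitivity (with only 12 stimuli the split-half
correlation estimate is too noisy for any implementation to separate
signal from noise reliably), and the full 1102-video stimulus count for
the memorability recovery, where the small per-voxel effect makes the
stimulus count the binding resource. The canonical 1000/102-video
schedule itself is cheap and is always built at full size.

## Known limitations

The FIR stage cannot produce trial-wise betas for the canonical 4 s
spacing (see above); regularised single-trial estimators that can are a
different method family and out of scope. The simulator's noise is
temporally AR(1) but spatially independent, so spatial statistics
(searchlight smoothness, cluster sizes) are not realistic. Atlas-based
dorsal ROIs are consumed as externally supplied masks; no atlas ships
with the package.
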