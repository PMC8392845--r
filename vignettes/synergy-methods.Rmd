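---
title: "Muscle synergy analysis of lower-limb sEMG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle synergy analysis of lower-limb sEMG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Surface electromyography (sEMG) of the thigh muscles — rectus femoris
(RF), femoral biceps (FB), vastus medialis (VM) and semitendinosus (SEM)
— carries information about how the central nervous system coordinates
the knee during movement. Raw multi-channel sEMG is too variable across
subjects to classify directly, but under the muscle-synergy hypothesis
the envelope signals of $m$ muscles are a non-negative mixture of a small
number $k$ of fixed muscle weightings:

$$A_{m \times n} \approx W_{m \times k} \, H_{k \times n},
  \qquad W \ge 0,\; H \ge 0,$$

where each column of $W$ is a synergy (a fixed recruitment pattern over
muscles) and the matching row of $H$ is its activation waveform. This
package implements the full analysis built on that model for three
lower-limb motions — leg flexion at standing (STD), leg extension at
sitting (ST) and level walking (Gait) — recorded together with a knee
goniometer at 1000 Hz, for control (CG) and knee-pathology (SG) subject
groups: preprocessing, angle-driven segmentation, synergy extraction,
synergy similarity, and synergy-feature classification of the motion
performed and of pathology status.

## Preprocessing and segmentation

Each raw channel passes a fourth-order Butterworth 20–450 Hz bandpass
(`filter_and_rectify()`), is zero-centered and full-wave rectified.
Filtering is applied forward–backward (zero phase) so the envelope stays
time-aligned with the goniometer trace; the amplitude response is
therefore the squared design response, which only sharpens the band
edges. Each muscle is normalized by its maximum over *all* of the
subject's movements (`session_maxima()`), and a centered 100 ms moving
RMS window extracts the envelope (`normalize_and_envelope()`; edge
windows shrink to the valid range). Envelopes are non-negative and lie
in $[0, 1]$.

Movement repetitions are located on the goniometer channel
(`segment_motion()`). The angle trace is smoothed by a 100 ms moving
average (the envelope smoothing scale; the protocol does not fix this
width) and angular speed taken as the central first difference. For
STD/ST, repetitions are bell-shaped excursions found by peak detection
with a minimum prominence of 20% of the angle range and 1 s separation
(rest periods of about 3 s separate repetitions). A repetition starts at
the first sample of the contiguous run of samples whose absolute speed
exceeds 10% of the initiating phase's speed maximum — located by
scanning back from the speed peak, which is identical to the forward
scan on clean traces but immune to goniometer noise during the preceding
rest — and ends at the first sample after the terminal-phase speed peak
where the speed falls back below 10% of that phase's maximum. Using
absolute speed with per-phase thresholds lets the same rule serve
flexion-first (STD) and extension-first (ST) movements. For Gait, cycle
boundaries are the first local angle minimum after each angle maximum
(the start of the support phase); segments span consecutive boundaries,
so $c$ cycles yield $c-1$ full segments when the recording ends in
standing rest. Segment envelopes are linearly resampled to 100 samples
(`resample_segment()`) before per-segment factorization.

## Synergy extraction and model order

`nmf_decompose()` minimizes the Euclidean cost $J = \lVert A - WH
\rVert_F$ with the Lee–Seung multiplicative updates. After every
iteration each column of $W$ is rescaled to unit Euclidean norm and the
matching row of $H$ by the inverse factor: the product $WH$ is unchanged
(so the monotone-descent guarantee is preserved) and synergy patterns
become comparable across subjects. The L2 norm is chosen because the
similarity measure below is correlation-based and scale-free; whether
the activation rows are compensated is a free choice and the
product-preserving one is adopted. Updates stop when the relative
decrease of $J$ over one iteration falls below `tol = 1e-6` or at
`max_iter = 1000`; denominators carry a $10^{-12}$ guard. Because
multiplicative updates only find local minima, each factorization is
restarted from 20 random initializations (entries uniform on $(0,1]$)
plus one non-negative double-SVD initialization (negative parts zeroed,
zeros replaced by `mean(A) * 1e-3`), and the run with the largest VAF
wins (ties: lowest run index, so a fixed seed gives bit-identical
results):

$$\mathrm{VAF} = 1 -
  \frac{\lVert A - WH \rVert_F^2}{\lVert A - \bar{A} \rVert_F^2},$$

with $\bar A$ the grand mean of $A$. `estimate_activation()` runs only
the $H$ update against a fixed $W$ (used when re-expressing segments
against a representative pattern). The synergy number per motion is the
smallest $k$ whose mean VAF across segments exceeds 0.85
(`select_synergy_number()`); the inner NMF loop is compiled (Rcpp /
Armadillo) because a full analysis factorizes thousands of small
matrices.

## Synergy similarity

The similarity of two pattern matrices is the maximum correlation
coefficient (`max_cc()`): for $W_1$ with $k_1$ columns and $W_2$ with
$k_2 \ge k_1$, every *ordered* selection of $k_1$ columns of $W_2$ is
formed and the Pearson correlation between the column-stacked matrices
computed; the maximum over selections makes the measure invariant to
synergy order. Ordered selections (not subsets) are enumerated so that
column correspondence is part of the maximization — feasible because
$k \le m \le 4$ here. Activation matrices are compared the same way over
their $k$ waveforms (they enter as samples × k). Intra-similarity of a
group is the mean max-CC over all unordered within-group pairs;
inter-similarity of two groups is the mean over the full cross-product
(`group_similarity()`).

`build_representative()` averages a subject's per-segment patterns into
one representative synergy after outlier removal: each matrix's mean
similarity $S_i$ to the others is computed, and matrices with
$|S_i - \bar S| \ge 3\delta$ are dropped ($\bar S$, $\delta$: mean and
standard deviation of the $S_i$). When $\delta = 0$ all matrices agree
and none is dropped — the strict reading of the keep-inequality would
delete everything, so the non-destructive reading is adopted. Note a
structural property of the rule: a lone outlier among $n$ values can
deviate at most $(n-1)/\sqrt{n}$ standard deviations from the mean, so
the rule can only ever fire in groups of at least 11 matrices. Before
averaging, survivors are column-aligned to the first survivor by the
max-CC matching (unmatched averaging across restart-permuted columns
would cancel structure); averaged columns are renormalized. The
representative activation is the mean of the per-segment activations
re-estimated against the representative pattern.

## Windowing, features, selection, classification

For classification, envelopes are cut into windows of 256 samples whose
starts step by 192 samples, i.e. 64 shared samples between neighbours
(`window_stream()`; the final partial window is discarded). Windows are
taken inside the detected motion segments by default so that rest
periods — which carry no motion information — contribute no training
rows; the full-envelope alternative is available
(`windows_from = "recording"`). Each window is factorized at the chosen
$k$ at its native 256-sample length (the 100-sample resampling belongs
to the per-segment similarity analysis, not to windowing).

Because restart order is arbitrary, synergies are reordered by
activation ratio $r_i = \mathrm{RMS}(h_i) / \sum_j \mathrm{RMS}(h_j)$,
largest first (`reorder_by_activation_ratio()`), before features are
extracted (`extract_features()`). The *coarse* set is the flattened
pattern matrix ($4k$ weights `W11..Wk4`). The *fine* set appends 8
time-domain features per activation row: RMS, the four coefficients of a
fourth-order autoregressive model $h_t = -\sum_{i=1}^4 a_i h_{t-i} +
e_t$ (Burg-fitted — standard for short sEMG windows; named `AR2..AR5`
with the trailing digit indexing the synergy), the interquartile range
(type-7 quartiles), waveform length $\sum_t |h_{t+1} - h_t|$ and mean
absolute value — 24 features for $k = 2$, 36 for $k = 3$. Constant
activation rows yield zero AR coefficients with a warning.

Feature selection is two-stage (`select_features()`). Stage 1 computes
Relief-F weights (`relieff_weights()`): iterating over every sample,
each feature's weight is decreased by the range-normalized distance to
the nearest same-class neighbour and increased by prior-weighted
distances to the nearest neighbour of every other class; one neighbour
per class, and features with negative weight are eliminated (zero
weights, e.g. constant features, are kept). Stage 2 is a sequential
floating forward search (`sffs_select()`): the spelled-out name in the
source protocol is the plain forward variant, but the cited algorithm is
the floating one with conditional backward elimination, which subsumes
it and is implemented here. The wrapper criterion is the mean
macro-averaged F-measure of a 30-tree random forest under seeded,
stratified, internal 5-fold cross-validation — deliberately distinct
from the outer 10-fold evaluation to avoid selection bias; ties break by
feature-name order and the search stops after 3 consecutive
non-improving additions. Evaluated subsets are cached (the evaluator is
deterministic given its seed).

Classes are rebalanced before training (`balance_resample()`): the
per-class target is the rounded geometric mean of the class counts;
larger classes are undersampled with replacement, smaller ones are grown
by ADASYN (5 nearest neighbours, synthesis weighted towards minority
points with many other-class neighbours, uniform weighting when the
class is cleanly separated, duplication fallback below 6 samples).
Evaluation (`cross_validated_fm()`) is seeded stratified 10-fold
cross-validation of a 30-tree random forest (Gini splits, $\sqrt{p}$
candidate features per split, unlimited depth); rebalancing is applied
to training folds only — test folds are never resampled. The reported
score is the mean over folds of the unweighted (macro) mean of per-class
F-measures $FM_i = 2 P_i R_i / (P_i + R_i)$; macro averaging is chosen
because rebalancing already removes the size imbalance the weighted
variant would re-introduce. Folds are stratified by window; a
subject-level grouping is a known stricter alternative (see
Limitations). The pathology task uses the identical pipeline with the
binary CG/SG label in place of the motion label.

## The synthetic cohort generator

`generate_recording()` produces raw recordings whose preprocessed
envelopes approximate a *known* factorization, so every downstream stage
is testable against planted ground truth. Per motion, the planted $W$
places a Gaussian bump of width $m/8$ channels (plus a 0.02 baseline) at
a motion-specific, synergy-staggered channel position, normalized to
unit columns; the bump width is chosen so the planted patterns are
genuinely distinct (pairwise correlations well below 1), which makes the
planted $k$ the true model order — the mean-VAF curves then sit in the
regime observed on real recordings (VAF just below 0.85 one order below
the planted $k$). The SG group's $W$ is shifted along a fixed
unit-norm direction by `group_shift`, clipped non-negative and
renormalized. Activations are temporally staggered Gaussian bumps per
movement. The raw signal per channel is the planted envelope (plus a
0.1%-of-peak sensor floor, plus optional Gaussian envelope noise
`noise_sd`) multiplied by band-limited (20–450 Hz) unit-variance carrier
noise — rectification and RMS smoothing then recover the envelope
without simulating motor-unit physiology. Angle traces are raised-cosine
bells of 6 s (2 s rise, 2 s hold, 2 s fall) separated by 3 s rests for
STD/ST, and cyclic traces with one clear minimum per 1.32 s cycle for
Gait, with the standing rest at 15° — above the 5° swing minimum, so the
final cycle still ends in a detectable minimum; both carry 0.2° sensor
noise. Defaults mirror the study protocol: 4 channels at 1000 Hz, 5
movements per recording, `noise_sd = 0.05`, `group_shift = 0.4` (a
clear but not degenerate pathology effect). Every recording derives its
own RNG stream from (seed, subject, motion), so cohorts are
bit-reproducible.

What the generator does *not* emulate: motor-unit action potentials and
their superposition statistics, electrode crosstalk, movement artifacts,
ECG contamination, within-subject fatigue drift, and the heterogeneous
pathologies of a real patient group (the SG shift is a single fixed
direction). Tests passing on this cohort therefore validate the
pipeline's mechanics and its recovery of planted structure, not clinical
performance on real sEMG.

## Numerical choices and degenerate inputs

- NMF: `tol = 1e-6` relative cost decrease, `max_iter = 1000`,
  denominator guard $10^{-12}$; restart ties broken by run index.
- Zero-variance matrices make the correlation undefined: `max_cc()`
  raises an error rather than returning NaN.
- Constant features have zero range; their Relief-F distance is defined
  as 0 and their weight stays exactly 0.
- Degenerate AR fits (constant rows) return zero coefficients with a
  warning; empty confusion rows/columns yield zero recall/precision
  rather than NaN.
- Flat angle traces segment to an empty list with a warning, not an
  error.
- Full-precision (17 significant digits) text serialization makes
  write-then-read round trips bit-identical.

## Problem sizes

The shipped tests and the reproduction script run the full pipeline on a
cohort of 2 subjects per group with 4 movements per recording (about
1000 windows), 20 seeded repetitions of the model-order recovery, and
10-fold outer cross-validation — sizes chosen so the whole suite
completes in minutes on a laptop while every stage still operates in its
intended regime. Larger cohorts only tighten the same estimates.

## Limitations

- Window-level cross-validation lets windows of one subject appear in
  both training and test folds; for subject-generalization claims a
  grouped split is required.
- The 3δ outlier rule cannot fire in groups of 10 or fewer matrices (see
  above); with few segments per subject it is effectively inert.
- The max-CC enumeration is factorial in the synergy count and is capped
  at 12 columns; high-density grids need an assignment-based matcher.
- VAF-threshold model selection inherits the threshold's arbitrariness;
  0.85 follows the source protocol.
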