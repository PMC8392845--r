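# emgsynergy

Muscle-synergy analysis and classification of multi-channel lower-limb
surface EMG (sEMG) in R.

## The problem

Clinically useful information about knee function is buried in
multi-channel thigh sEMG — rectus femoris (RF), femoral biceps (FB),
vastus medialis (VM) and semitendinosus (SEM) — recorded together with a
knee-angle goniometer while subjects flex the leg while standing (STD),
extend it while sitting (ST), or walk (Gait). Raw sEMG varies too much
across subjects to classify directly. Under the muscle-synergy model the
non-negative envelope matrix of `m` muscles factorizes as

    A (m x n)  ≈  W (m x k) · H (k x n),   W ≥ 0, H ≥ 0

where each column of `W` is a *synergy* — a fixed recruitment weighting
of muscles — and the matching row of `H` is its activation waveform.
`emgsynergy` implements the complete pipeline built on this model, for
researchers working on sEMG-based motion recognition and knee-pathology
screening:

- **Preprocessing** — 20–450 Hz zero-phase Butterworth filtering,
  rectification, per-session amplitude normalization, 100 ms moving-RMS
  envelopes (`filter_and_rectify()`, `normalize_and_envelope()`).
- **Segmentation** — movement repetitions located on the goniometer
  trace via 10%-of-peak-speed crossings (STD/ST) or angle minima after
  each maximum (Gait) (`segment_motion()`).
- **Synergy extraction** — multiplicative-update NMF (compiled inner
  loop) with per-iteration column normalization, 20 random restarts plus
  a non-negative-SVD start, winner by variance accounted for (VAF), and
  model-order selection by the smallest `k` with mean VAF > 0.85
  (`nmf_decompose()`, `select_synergy_number()`).
- **Similarity** — synergy matching by the maximum correlation
  coefficient over ordered column selections, intra/inter-group
  similarity tables, and outlier-robust representative synergies per
  subject (`max_cc()`, `group_similarity()`, `build_representative()`).
- **Classification** — 256-sample windows (step 192), per-window NMF
  features (synergy weights plus RMS/AR(4)/IQR/waveform-length/MAV of
  the activations), two-stage Relief-F + floating forward selection,
  ADASYN/undersampling rebalancing to the geometric-mean class size, and
  a 30-tree random forest under stratified 10-fold cross-validation with
  macro F-measure reporting (`classify_cohort()` and friends).
- **Synthetic cohorts** — a generator that plants known `W`/`H`
  structure, bell-shaped or cyclic knee-angle traces and a controllable
  between-group synergy shift, so the whole pipeline is testable without
  any data download (`synth_spec()`, `generate_cohort()`).

## Worked example

```r
library(emgsynergy)

# a small synthetic cohort: 2 subjects per group, 4 movements each
spec   <- synth_spec(n_subjects = 2, reps = 4, seed = 101)
cohort <- generate_cohort(spec)
pr     <- preprocess_cohort(lapply(cohort, `[[`, "recording"))

# synergy structure per motion
ana <- motion_synergy_analysis(pr, seed = 1)
unlist(ana$k)
#> STD  ST Gait
#>   2   2    3
round(ana$mean_vaf$Gait, 3)
#> [1] 0.317 0.747 0.999
mean(ana$gait_durations)
#> [1] 1.303167

# motion classification from per-window synergy features (k = 2)
fine <- classify_cohort(pr, task = "motion", k = 2, features = "fine",
                        seed = 11)
fine$mean_fm
#> [1] 0.914485
```

The selected synergy numbers say that the two isolated knee motions are
explained by two synergies while walking needs three (the mean VAF at
one order lower, 0.747, fails the 0.85 rule). The detected gait segments
average 1.30 s against a planted 1.32 s cycle. The cross-validated
macro F-measure of 0.91 means windows of the three motions are
recognized nearly perfectly from their synergy features alone.

A thin CLI mirrors these steps (`exec/emgsynergy`):

```sh
emgsynergy simulate --out cohort/ --subjects 2 --reps 4 --seed 101
emgsynergy synergy  --manifest cohort/manifest.csv
emgsynergy classify --manifest cohort/manifest.csv --task motion \
    --k 2 --features selected --out report.json
```

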