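---
title: "Measuring auditory household chaos: models, detector and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring auditory household chaos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Household chaos — a home environment high in noise and crowding and low in
regularity — predicts a range of child developmental outcomes, but is
usually measured by one-shot questionnaires. `chaoscope` implements an
automated, fine-grained alternative: every non-overlapping 5-second
segment of a daylong child-worn audio recording is classified into one of
four ordinal *auditory chaos* levels:

| Level | Meaning | Typical sounds |
|-------|---------|----------------|
| 0 | Silence or absence of sound | — |
| 1 | Soft daily or familiar sounds | calm conversation, white-noise machine, quiet music |
| 2 | Slightly stimulating sounds | raised voices, vacuum cleaner, toy music |
| 3 | Highly stimulating, scary or jarring sounds | shouting, wailing, crashes, alarms |

Two practical obstacles shape the package design. First, level-3 events
are rare in the wild, so naive annotation wastes most annotator time; a
*high-chaos detector* triages candidate segments before human labeling.
Second, classifiers must generalise across families, so all evaluation is
leave-one-participant-out (LOPO).

All audio follows one contract: mono PCM, 22,050 Hz, in `[-1, 1]`;
segments are exactly 110,250 samples. A recording of duration `d` seconds
yields `floor(d/5)` segments (the trailing remainder is dropped — with
411.2 h of audio this floor rule reproduces the expected 296,064-segment
total exactly, and one hour holds 720 segments).

## Acoustic features

Framewise features use a sliding window of 512 samples with a 256-sample
hop, *centered* (the signal is zero-padded by half a window at each
edge). Centered framing is a deliberate choice: it is the only convention
under which a 5-s segment yields the canonical 431 frames
(`1 + floor(110250/256)`); left-aligned framing would give 429.
A side effect worth knowing: for a constant-amplitude signal the two edge
frames include zero padding, so framewise standard deviations are small
but not exactly zero.

* **RMSE** — root-mean-square energy per frame. Per-participant mean RMSE
  (over *all* frames of the entire recording) is the loudness normaliser:
  the detector treats a segment as "very loud" when any frame exceeds 7×
  that mean, and disambiguates cry vs. babble at 3×.
* **Spectral flatness** — geometric/arithmetic mean ratio of the power
  spectrum (Hann window, power floored at `1e-10`). Near 1 for noise,
  near 0 for tones; "all 431 values above `1e-4`" is the white-noise
  signature used to prune spurious vehicle predictions.
* **Zero crossings** — segment-level count of sign changes; a pass
  through exact zero counts once (`+a, 0, -a` is one crossing). Counts
  between 1,000 and 4,000 over 5 s mark unvoiced noisy audio.
* **The 53-feature vector** — mean and standard deviation (population
  convention, denominator *n*) over frames of 26 framewise features
  (20 MFCCs, zero-crossing rate, flatness, rolloff at 85%, centroid,
  bandwidth, RMSE), plus segment peak amplitude. The order is fixed:
  `mean_mfcc_1..20, mean_zcr, mean_flatness, mean_rolloff,
  mean_centroid, mean_bandwidth, mean_rmse`, the same 26 as `sd_*`, then
  `peak_amplitude`. MFCCs use a 40-filter HTK-style mel bank over
  0–11,025 Hz, decibel compression and an orthonormal DCT-II; these
  filter-bank details are not dictated by any external constraint, so
  they are fixed here as configuration for reproducibility.
* **Log-mel patches** — each 5-s segment is chunked into 2-s patches
  (2 s, 2 s, and a 1-s tail replicated to 2 s); each patch becomes a
  96-band log-mel spectrogram (40-ms window, 50% overlap, FFT size 1024,
  natural log floored at `1e-10`), a 96 × 101 matrix.

The test suite pins these operations to independent brute-force oracles:
explicit per-frame loops with manual padding and a direct DFT, never the
implementation's own code path.

## The high-chaos detector

The detector consumes per-segment (class, confidence) tables from an
external everyday-sound classifier (e.g. a 521-class model consuming
16 kHz mono audio); the package never requires that model — synthetic
prediction tables with controlled error rates stand in during testing.
The pipeline per segment:

1. **Class grouping.** Classes with an annotation-quality estimate at or
   below 33%, and classes implausible in infant-worn home recordings,
   are dropped; the remainder are manually mapped to *high* vs
   *non-high* chaos groups. The table shipped in
   `inst/extdata/class_metadata.csv` covers an illustrative subset; real
   deployments supply their full class list in the same format.
2. **Top-k / confidence floor.** Only the ten most confident predictions
   are kept, and none below 0.01% confidence (`1e-4`).
3. **Cry/babble pruning.** Crying carries far more energy than babbling,
   so when both appear: keep cry and drop babble if any frame RMSE
   exceeds 3× the participant mean, else the reverse.
4. **White-noise/vehicle pruning.** If the segment looks like unvoiced
   noise (all flatness values above `1e-4`, *or* zero crossings in
   [1000, 4000]) and carries a vehicle-like prediction, the vehicle
   prediction is dropped. We read the rule's precedence as
   `(flatness OR zero-crossing band) AND vehicle-like`, and "dropped"
   as dropping the *prediction*, not the segment — consistent with this
   stage's purpose of pruning the prediction list. Both readings are
   localised in `prune_whitenoise_vehicle()` if a user wants the other.
5. **Candidate selection.** A segment is a candidate if any surviving
   prediction maps to the high group, *or* — irrespective of
   predictions, including an empty table — any frame RMSE exceeds 7×
   the participant mean (the loudness override). The RMSE comparisons
   use raw frame values, not post-pruning quantities.

Efficiency is scored as recall/precision for true level-3 segments, the
flagged fraction, and the *enrichment factor*: the high-chaos rate among
candidates divided by the rate in a per-participant size-matched random
sample. On synthetic streams with miss rate $m$, false-alarm rate $f$
and level-3 prevalence $p$, prediction-driven detection obeys the Bayes
relations $\mathrm{recall} \approx 1 - m$ and
$\mathrm{precision} \approx \frac{p(1-m)}{p(1-m) + (1-p)f}$,
which the acceptance tests verify over five seeds.

## The three classifiers

* **RF-3f** — a 1000-tree probability forest on (mean RMSE, sd RMSE,
  peak amplitude): the volume-only baseline testing whether loudness
  alone can measure chaos.
* **RF-53f** — the same forest on the 53 acoustic features.
* **CNN** — a compact pre-activation network over log-mel patches:
  three 5×5 convolutions, each preceded by BatchNorm → ReLU, two
  interleaved max-pooling stages, and two dense layers ending in a
  4-way softmax. Widths 24/48/96 with a 112-unit dense layer give
  532,550 trainable weights (the builder rejects configurations outside
  0.3–0.7 M). Training uses categorical cross-entropy, batch size 64,
  Adam at 0.001, and early stopping on validation accuracy with
  patience 15, restoring the best weights.

Design choices the architecture leaves open were fixed as follows. The
first convolution uses stride 2: at a 96 × 101 input this halves the
spatial grid before the channel count grows, a standard arrangement for
spectrogram classifiers that leaves the parameter count unchanged
(convolutional and dense parameter counts are independent of stride).
Pooling windows are 4×4 then 2×2, bringing the grid to 6 × 6 before the
dense head. The validation split for early stopping holds out whole
participants (about 10% of patches) when at least five participants are
available, else a class-stratified random 10%. BatchNorm running
statistics are seeded from the first batch and then tracked with
momentum 0.8 — with the small number of batches per epoch used here, the
conventional 0.9–0.99 momenta would leave inference statistics stale for
many epochs. The whole network, including backpropagation and Adam, is
implemented in vectorised R (im2col + BLAS GEMM); a finite-difference
gradient check in the test suite guards its correctness.

Segment-level predictions aggregate the per-patch probability vectors by
element-wise geometric mean, floored at `1e-12` so a single zero cannot
annihilate a class, renormalised to sum to 1. Ties at the argmax resolve
to the *lowest* chaos level — the conservative choice for an instrument
meant to flag stimulation.

## Evaluation protocol

* **Balanced training sets.** Before every fit, an equal time budget per
  chaos level is sampled from non-test participants. Level 0 (silence)
  is the only class sampled with repetition: every available level-0
  segment enters at least once and the remainder is drawn with
  replacement, since repeating silence does not change the class. Any
  other class falling short of the budget is a hard error. The deployed
  10 h/class budget generalises to
  `max_balanced_budget()`: the largest budget every LOPO fold can
  satisfy without repetition, which is how the experiments in this
  package pick their budgets.
* **LOPO-CV.** One fold per participant; the fold's balanced training
  set never contains the held-out participant (asserted at runtime).
  Fold predictions are pooled for global macro and weighted
  precision/recall/F1; classes absent from both truth and prediction are
  excluded from the macro mean rather than scored zero (the same rule
  that drops level 0 from the Cry-set evaluation), and the exclusion is
  recorded on the result object.
* **Paired comparisons.** Participant-specific *weighted* F1 scores
  (macro scores are too noisy at under 5 minutes of data for some
  participant-classes) feed two-sided paired t-tests at α = 0.05,
  without multiple-testing correction, mirroring how such pairwise model
  comparisons are conventionally reported. Zero-variance nonzero
  differences are flagged as degenerate rather than reported as
  infinite statistics.
* **Cry/Non-cry split.** Segments whose sound-event table carries a
  cry-like class form the Cry set; within it, segments predicted level 0
  are dropped before scoring (there are too few to evaluate and they
  would distort macro metrics).
* **Ablation.** `run_ablation()` re-runs balanced-sample → LOPO-CV over
  a grid of training sizes (deployed grid: 40/20/10/5 h × 3 runs = 12
  experiments), sharing folds across sizes within a run for variance
  reduction, and reports pooled metrics per size.

## The synthetic soundscape generator

Real infant-worn home recordings are access-restricted, so the package
ships a seeded generator that emulates the *structure* the pipeline
assumes. Source recipes: tones (200–2,000 Hz), harmonic stacks (3–6
partials), "speechlike" band-limited noise with 3–8 Hz amplitude
modulation, white noise, and exponentially decaying broadband impulses.
Level recipes: level 0 is near-silence (peak ≤ 0.01 full scale — an
unambiguous machine-checkable reading of "absence of sound"); level 1
mixes 1–2 soft tonal sources; level 2 adds speechlike modulated noise;
level 3 is a dense cacophony of 4–6 sources with impulses. Amplitude
ranges rise with level in the default ("easy") condition, as they do in
real homes.

The *volume-confounded* condition exists to reproduce the motivating
claim that volume alone cannot measure chaos: level 1 becomes a loud
steady white-noise machine, level 3 a quiet dense cacophony, and all
non-silent levels share a common loudness distribution (random slow
amplitude envelopes plus RMS-matched gain). Volume is not perfectly
uninformative even then — crest factor differs physically between steady
noise and impulsive cacophony — so the volume baseline sits above chance
among levels 1–3 (restricted macro F1 around 0.5 against a chance level
of 1/3) but far below the spectral models (around 0.98): the qualitative
ordering of interest. Level 0 remains trivially separable by silence in
both conditions, by definition of the class.

Prediction-table noise is controlled by four rates: missed high-chaos
classes, false high-chaos alarms, joint cry/babble confusions, and
spurious vehicle labels on white-noise segments — the error modes the
pruning heuristics exist for.

Every generator call takes an explicit seed and leaves the caller's RNG
state untouched; identical inputs give bit-identical waveforms, also
after a 16-bit WAV round trip.

**What passing tests do and do not show.** The generator's classes are
spectrally well separated and stationary within a segment; real home
audio has overlapping semantics (a lullaby over a crying infant),
channel effects, and annotator judgment. Recovery of synthetic labels
therefore validates the machinery — features, models, cross-validation
plumbing, metrics — not real-world accuracy.

## Problem sizes used by tests and the acceptance script

The shipped experiments run on three synthetic participants of 0.1 h
each (72 segments per participant, 216 in total per condition), chosen
so a full balanced-sampling → CNN → LOPO-CV cycle completes on a single
CPU in minutes while leaving every class with dozens of training
segments per fold. Per-class budgets come from `max_balanced_budget()`
(typically 25–35 segments per class); the CNN trains for up to 10 epochs
in these runs (the separable condition converges by epoch 4–6; the
early-stopping patience of 15 governs longer runs). The ablation grid
scales the deployed 40/20/10/5 h geometric ladder down to the same
dataset (halving per step from the feasible maximum), keeping the
3 × 4 = 12-run design. The numbers the README quotes are produced by
these same runs.

## Known limitations

* The synthetic generator makes no attempt at acoustic realism (no
  speech, no room acoustics, no recorder characteristics); it is a
  structured fixture, not a simulator.
* The shipped class-metadata table is an illustrative subset; the full
  class-to-chaos-group mapping of a 521-class sound vocabulary is
  user-supplied configuration.
* The CNN engine is CPU-bound R; it is sized for the package's
  experiment scales, not for training on hundreds of hours of audio.
* Crest-factor leakage keeps a volume-only model above chance in the
  confounded condition, as discussed above.
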