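---
title: "Methods: quantifying zebra vocal repertoire and individuality"
author: "zebrarep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying zebra vocal repertoire and individuality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`zebrarep` implements a complete analysis chain for the vocal repertoire
and vocal individuality of plains zebras (*Equus quagga*), a species whose
repertoire comprises at least four call types: the pulsed, broadband
**snort**; the softer, white-noise-like **soft snort**; the tonal,
high-fundamental **squeal**; and the multi-unit contact call
**quagga quagga** ("a-ha"). The chain runs from annotated WAV recordings to
(i) supervised call-type classification from acoustic features and from
mel-spectrograms, (ii) unsupervised call clustering, and (iii) a nested
permuted discriminant function analysis (pDFA) of individual identity.
Because field recordings are not redistributable, the package ships a
synthetic-call generator with known ground truth that emulates the
statistical structure of such a dataset; every stage is validated against
that ground truth.

## The acoustic feature set

Twelve features are extracted per call after a per-type high-pass filter
(30 Hz for the two snort types; 500 Hz for squeals; 600 Hz for
quagga quagga — just above the average minimum fundamental of the tonal
types). The filter is a zero-phase (forward–backward) 4th-order
Butterworth; zero-phase filtering is used so the amplitude envelope, on
which three of the features depend, is not smeared by filter delay.

* **F0 statistics** (mean, max, min, range; tonal calls only): a
  frame-wise autocorrelation pitch tracker (40 ms frames, 10 ms hop)
  searching a per-type range (squeal 400–4000 Hz, quagga quagga
  400–3000 Hz), with parabolic peak interpolation and a voicing threshold
  of 0.45 on the normalized autocorrelation peak. These settings are
  declared defaults in the tradition of Praat's pitch object, not
  inferences from data; they recover constant-F0 test tones to well under
  1%.
* **Spectral energy quartiles and peak frequency**: a single DFT of the
  whole filtered call (rectangular window); `q_p` is the smallest
  frequency at which cumulative energy reaches `p` of the total, and the
  peak frequency is the maximum-power bin. The whole-call spectrum
  matches the convention of quartiles computed on a sound object rather
  than per frame.
* **Amplitude metrics**: the intensity contour is frame RMS in dB (10 ms
  frames, 5 ms hop). *Amplitude variation* is cumulative |ΔdB| divided by
  duration. *AM rate* counts complete envelope excursions
  (extremum → extremum → extremum) detected by hysteresis tracking with a
  3 dB prominence, divided by duration; *AM extent* is the mean dB swing
  between consecutive committed extrema. Two conventions matter and are
  deliberate: the trailing candidate extremum is committed when the
  contour ends (its excursion already exceeded the prominence), which
  removes a −1-cycle bias and keeps AM extent defined for single-swell
  envelopes such as soft snorts; and the two envelope frames touching
  each edge are excluded from cycle counting, so onset/offset ramps are
  not mistaken for modulation — a call with a genuinely flat interior
  envelope therefore reports `am_rate = 0` and a missing `am_extent`, the
  situation in which real squeals are excluded from the feature-based
  repertoire set.

The repertoire analyses use the 8-feature subset without the F0
statistics, which non-tonal calls lack; the individuality analysis uses
all features that are defined for the call type under study.

## Spectrogram preparation and the time-shift distance

Mel-spectrograms use 128 bands, a 512-sample Hann window, 256-sample hop,
30 Hz–Nyquist, in dB relative to each call's maximum and floored at
−80 dB. "Zero padding" is interpreted as zero *power*, i.e. the dB floor;
literal zeros on a dB scale would inject mid-level energy. Calls longer
than 1.25 s are excluded from spectrogram-based analyses (the repertoire
inclusion rule; the bound is strict, a 1.25 s call is kept). All matrices
in a set are onset-aligned (first frame more than 10 dB above the floor
moves to frame 0) and right-padded to the longest call.

The spectrogram distance is the minimum Frobenius distance over integer
frame shifts within ±`max_shift` (default 25% of the width), vacated
frames filled with the floor. It is exactly zero for a call and its
shifted copy whenever the shift is inside the window, and equals a
brute-force shift loop by construction; both properties are tested.

## Supervised classification

*Features*: candidate features are screened by Shapley-value importance
from a gradient-boosted tree model — a feature is kept when its mean
absolute SHAP attribution, summed over the class outputs, exceeds 1. The
classifier itself is gradient boosting on a stratified 70/30 train/test
split, with learning rate, tree depth and tree count tuned by a random
search (default 20 trials) with 5-fold cross-validation on the training
split only. The search is a desk-scale stand-in for a full hyperparameter
optimization: procedure parity, not budget parity.

*Spectrograms*: a compact convolutional network — two 3×3
convolution + ReLU + 2×2 max-pool blocks, a 32-unit dense layer, softmax —
on 49/21/30 train/validation/test splits, trained with Adam and early
stopping on validation loss. Inputs are mean-pooled to 32×32 and min–max
scaled over the whole set. The network is implemented directly on matrix
operations (im2col convolution), which keeps training deterministic under
a seed and easily fast enough at these input sizes.

Both models are reported with accuracy, per-class precision/recall/f1 and
the confusion matrix, computed on the held-out test split only.

## Unsupervised clustering

Calls are embedded in 2-D by a neighbor-graph spectral embedding: a
k-nearest-neighbor graph (default `n_neighbors = 50`) on the chosen metric
(Euclidean on standardized features, or the time-shift distance for
spectrograms) with locally adaptive Gaussian edge weights — each call's
kernel width is its median distance to its neighbors — plus a faint global
affinity term (weight 1e−6) that keeps the graph connected; the two
leading non-trivial eigenvectors of the symmetric normalized Laplacian are
the coordinates. Two design points deserve explanation:

* A *global* embedding (classical MDS) preserves the dominant
  tonal/non-tonal macro-contrast and, in two dimensions, discards the
  axes separating the remaining types. Neighbor-graph methods instead
  equalize the separation of well-isolated groups, which is the behavior
  that makes a cluster-count analysis of the embedding meaningful.
  `n_neighbors` should stay below the expected size of one call-type
  group; the default of 50 assumes groups of roughly a hundred calls or
  more.
* The connectivity term matters because with fully disconnected graph
  components the Laplacian null space is degenerate and two groups can
  collapse onto the same 2-D coordinate.

k-means is run on the embedding for k = 1…8 and the cluster count chosen
at the **elbow of the log-inertia curve**: the k maximizing the discrete
second difference of log within-cluster sum of squares, with k = 1
declared when the strongest elbow ratio `I(k−1)·I(k+1)/I(k)²` is below 3.
The log scale makes the rule scale-invariant — a bend that follows an
already-large drop still registers, where the absolute-scale second
difference provably locks onto the macro-split of a hierarchical
geometry — and the strength floor lets a structureless single blob report
one cluster. Diagnostics are the row-normalized type-by-cluster table and
the distributions of pairwise distances within versus between call types,
summarized by a histogram overlap coefficient.

## The individuality chain

For one call type at a time: Kaiser–Meyer–Olkin screening keeps features
with sampling adequacy MSA ≥ 0.5 (MSA compares squared correlations with
squared anti-image partial correlations from the inverse correlation
matrix); PCA on the correlation matrix keeps components with
eigenvalue > 1; a discriminant function analysis with individual identity
as the grouping factor reports each DF's share of discriminative variance
and its correlations with the PC scores, flagged at |r| ≥ 0.5.

The nested pDFA then tests individual distinctiveness while controlling a
restriction factor (sex or location) under which individuals are nested:

1. For each of `n_selections` (default 100) draws, an equal number of
   calls per individual — `max(2, floor(0.6 × minimum per-individual
   count))` — forms the derivation set; a pooled-covariance linear DFA
   fitted on it classifies the withheld calls; the observed statistic is
   the mean number classified to the correct individual.
2. The null shuffles the call-to-individual assignment only among
   individuals sharing a restriction level, preserving per-individual call
   counts, and recomputes the statistic; the observed dataset counts as
   one of the `n_permutations` (default 1000), so the smallest attainable
   p-value is 1/1000 — the printed form of strongly significant results.
3. The chance level is the mean permuted statistic; percentages divide
   both statistics by the number of withheld calls.

The internal LDA uses the classical pooled within-group covariance with a
ridge of 1e−8 for numerical safety and equal priors (derivation sets are
balanced by construction); classification ties break toward the lowest
individual index so runs are reproducible. The implementation is
cross-checked in the test suite against an independent reference LDA on
the same data.

Design notes: each individual needs at least 5 calls of the type under
analysis (the inclusion rule; enforced by the workbench filter) and
mechanically at least 3 so both derivation and withheld sets are
non-empty. A restriction level containing a single individual contributes
nothing to the null and triggers a warning; a single level overall reduces
to an unrestricted pDFA. The permutation mean is taken over permuted
datasets only, keeping the "expected number correct" a pure chance
estimate.

## The synthetic-call generator

The generator emulates the *statistical* structure of an annotated
field dataset — not the sound of a zebra. Call models follow the field
descriptions of the four types:

* squeal: harmonic stack (6 harmonics, −6 dB/octave) on a smoothly
  rising–falling F0, base 1200 Hz, with sinusoidal AM (20 s⁻¹, 8 dB). The
  AM rate was fixed so the shortest squeals (0.3 s) still carry enough
  complete cycles for a cycle-counting estimator to resolve the rate.
* quagga quagga: 3–6 tonal units at a 700 Hz base, alternating
  exhale/inhale units (every second unit 20% higher), separated by silent
  gaps (~35% of the call).
* snort: spectrally tilted noise (−3 dB/octave) with raised-cosine
  amplitude pulses at 25 s⁻¹ (20 dB deep), starting at a trough so the
  onset ramp never clips a pulse peak.
* soft snort: white-noise-like (0 dB/octave) with a single smooth swell,
  12 dB below the snort. The flat tilt follows the description of the
  type as resembling white noise and is what separates it spectrally from
  the snort.

Individual vocal signatures are additive per-individual offsets drawn once
per individual (F0 SD 120 Hz, AM-rate SD 4 s⁻¹, tilt SD 0.8 dB/octave) and
shared across that individual's call types; call-to-call noise uses the
within-individual SDs (40 Hz, 1.5 s⁻¹, 0.3 dB/octave). The tilt SDs are
deliberately small relative to the snort/soft-snort tilt contrast:
individuals perturb, and must not span, the type differences — call types
are recognizable by ear across individuals. Optional additive sex and
location effects support the nested designs; setting every
between-individual SD to zero gives the null model. Pink-ish background
noise is added at 30 dB SNR (an invented convention — the field data's
amplitude statistics are unknown) so that high-pass filtering matters.
Durations are uniform within per-type ranges capped at 1.25 s.

What the generator does *not* emulate: reverberation and propagation,
graded or combined call types (no "squeal-snort"), amplitude cues
(features are scale-invariant by design, so the soft snort's lower level
is informative only through its envelope shape), and any natural
covariance between features beyond what the shared per-individual offsets
induce. Passing tests on synthetic data therefore demonstrate the
correctness and calibration of the *methods*, not field-data performance.

## Problem sizes and numerical choices

The validation experiments run at a scaled-down version of the study's
shape: 12 individuals × 4 call types × 15 calls (720 calls) for repertoire
analyses, chosen to keep a full run on one CPU comfortable while leaving
every per-type sample (180) far above the classifier splits' needs.
pDFA calibration uses 200 null replicates at 200 permutations and 10
selections, generated at the ground-truth-parameter level by the
generator itself (`write_audio = FALSE`): under the null the generating
parameters are exactly the quantities the feature extractor estimates, so
this isolates the test's calibration from extraction noise at a small
fraction of the cost of re-synthesizing audio hundreds of times; the
audio-level null is covered once by a variance-decomposition test. Power
is summarized as the median observed count over 10 seeds at three effect
sizes (0.5×, 1×, 2× the default SDs).

Degenerate inputs are handled explicitly: zero-energy signals are
rejected with a named reason and logged per call rather than aborting a
batch; k-means on identical points forces k = 1; a singular correlation
matrix in KMO names the collinear variables; classification ties break
deterministically.

## Known limitations

* The pitch tracker is a plain autocorrelation method without octave-cost
  heuristics; it is accurate on clean harmonic stacks but would need care
  on noisy field recordings with strong subharmonics.
* The spectral embedding reproduces the *qualitative* behavior of
  manifold embeddings (cluster equalization), not any specific published
  layout; its `n_neighbors` is not numerically comparable to parameters
  of other methods.
* The elbow strength threshold (3) is a heuristic; borderline hierarchical
  data near the threshold can flip between a coarse and a fine cluster
  count.
* The CNN is intentionally small; it is a faithful, tested stand-in for
  the architecture class, not a tuned production model.
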