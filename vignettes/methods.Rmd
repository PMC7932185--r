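---
title: "Decoding word semantics from MEG during speech planning: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding word semantics from MEG during speech planning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megdecode)
```

## The question and the design

During picture naming, the brain plans a word several hundred milliseconds
before articulation. `megdecode` asks whether the *semantic identity* of the
planned word can be read out from MEG sensor patterns, and whether the
underlying neural code is stable across time and across naming contexts:
producing a word alone ("lamp"), inside a two-word list ("green, lamp"), or
inside an adjective–noun phrase ("white lamp").

The experimental design the package generates and analyses crosses five
object shapes (bag, bell, cane, lamp, plane) with five color terms (black,
brown, green, red, white). Twenty-five base images pair every shape with
every object color; backgrounds are assigned by a per-shape rotation of the
color list (so backgrounds are counterbalanced: each color backs ten images,
twice per shape), and swapping object and background colors yields the
complementary 25, for 50 images closed under the swap. Each of five blocked
naming conditions (adjective, noun, list, phrase, color-control) presents
all 50 images twice — 100 trials per condition, 500 in total — in blocks of
25, with block order randomized under the constraint that two blocks of the
same condition are never adjacent. The color-control condition is generated
for completeness but carries no unambiguous per-category word label and is
not decoded.

## The decoding model

Epochs span −100…700 ms around picture onset at 1000 Hz over `c` sensors
(208 at full scale). After preprocessing, same-word epochs are averaged in
random groups of 5, giving `N = 20` averaged epochs (5 words × 4) per
condition and category. For a 100-sample window the sensors × time slab of
each averaged epoch is flattened (sensor-major) into a row of
`X ∈ R^{N×p}`, `p = c·t`; every column of `X` is normalized to mean 0, sd 1
(population convention, training rows only) and a ones column is appended
for the bias. With `Y ∈ R^{N×d}` the word-embedding matrix (one identical
row per same-word epoch), the decoder fits `d` independent ridge
regressions

  `h_j(X) = X w_j`,  `w_j = (XᵀX + λ_j I)⁻¹ Xᵀ y_j`,

selecting `λ_j` per embedding dimension from a grid (default 13 log-spaced
values, 10⁻⁴…10⁸) by leave-one-out cross-validation. Because `N ≪ p`, one
thin SVD of the design is shared across all grid values and output
dimensions, and the LOO errors come from the exact hat-matrix identity
`e_i/(1 − H_ii(λ))` rather than `N` refits; ties in the LOO error go to the
smallest `λ`.

Two deliberate choices where conventions differ:

* **Bias penalty.** The textbook formula above penalizes the full `w`,
  including the appended ones-column weight. The default here excludes the
  bias from the penalty (standard practice; with column-centered features
  the difference is negligible and the intercept stays unbiased). The
  estimator with the literal formula is available via
  `penalize_bias = TRUE`, and both paths are tested against direct dense
  solves.
* **Normalization scope.** Column statistics are computed from the training
  rows only and applied to held-out rows, avoiding leakage through the
  leave-2-out split; `normalization = "global"` (statistics from all `N`
  rows before splitting) is provided because the original description of
  the procedure is compatible with either reading.

## Evaluation: the 2-vs-2 test

Decoders are scored by the 2-vs-2 test: hold out two averaged epochs with
*different* word labels, train on the remaining `N − 2`, and check

  `d(ŷ_a, y_a) + d(ŷ_b, y_b) < d(ŷ_a, y_b) + d(ŷ_b, y_a)`

under cosine distance, awarding 1 / 0 / 0.5 (equality within 10⁻¹²). Pairs
with equal labels are vacuous (both sides coincide) and are excluded: with
5 words × 4 averages, 160 of the 190 pairs are valid. Accuracy at a window
is the mean score over all valid pairs; chance is 0.5.

Sliding the 100 ms window in 5 ms steps across the epoch yields an accuracy
time course (window centers −50…650 ms, 141 windows at full scale; windows
are half-open `[start, start + 100 ms)` and labelled by their *center* —
the original report does not say whether its times index starts, centers,
or ends, and centers are the reading consistent with effects reported at
650 ms in epochs ending at 700 ms).

Temporal generalization matrices (TGMs) decouple training and testing
windows: `M_ij` is the accuracy of a decoder trained at window `i` and
tested at window `j`. Within a condition the same two epochs are left out
of both windows, so `M_ii` reproduces the same-window curve bit-exactly.
Across conditions (e.g. train on nouns in isolation, test on nouns in
phrases) the train and test epochs come from disjoint trial sets, so the
decoder is trained on all `N` training-context epochs — no leave-out is
needed — and scored on every valid pair of the test context. (Whether the
original analysis excluded any training epochs in the across-condition case
is not documented; the disjoint-trials argument motivates this contract.)

## Statistical inference

* **Permutation null.** The epoch-to-word mapping is shuffled 100 times and
  the full normalize/fit/score evaluation re-run per shuffle; the mean
  shuffled accuracy sits at chance (50%). Shuffling is applied at the
  averaged-epoch level by default — shuffling raw trials and re-averaging
  mixed-word groups is statistically equivalent under the null and
  costlier — with `level = "raw"` available. A Gaussian kernel density
  (Silverman's rule, the `bw.nrd0` bandwidth) fitted to the null gives
  one-sided upper-tail p-values, computed exactly as the mean Gaussian tail
  over kernels.
* **FDR.** P-values along one time course (or one TGM's cells) form one
  correction family and are corrected by Benjamini–Yekutieli step-up (valid
  under arbitrary dependence), via `stats::p.adjust(method = "BY")`.
* **Factorial effects.** Per time point, participant accuracies enter a
  balanced two-way fixed-effects ANOVA (2 word categories × 3 contexts, or
  targeted 2 × 2 contrasts). Clusters of ≥ 3 adjacent points with
  `p < 0.05` receive a mass equal to their summed F-values; significance
  comes from permuting the category/context cell labels within each
  participant (10,000 times at full scale) and comparing each window's
  largest observed cluster against the permutation distribution of maximum
  cluster mass, with the `(1 + x)/(n + 1)` correction so p-values are never
  zero. Search windows default to 0–400 and 400–650 ms (earlier and later
  effects). Ties among "largest" clusters break to the earliest onset. The
  ANOVA is implemented as vectorized balanced sums of squares (the
  permutation scheme re-evaluates it thousands of times per effect); it is
  verified against `stats::aov` to 10⁻⁸ in the tests. Whether the original
  pointwise test was repeated-measures or fixed-effects is not documented;
  the within-participant permutation scheme, which is what licenses the
  cluster p-values, is reproduced exactly.

## The synthetic-data generator

No recordings are distributed with the original analysis, so the package
ships a generator that emulates the statistical structure the decoding
method assumes, making every downstream stage testable end to end:

* **Signal.** Each epoch is `Σ_words (A y_w) g_w(t)`: the planned words'
  embeddings projected into sensor space by a participant-specific mixing
  matrix `A` (entries `N(0, 1/d)`) and modulated by a raised-cosine
  envelope, active 100–400 ms by default — the latency range in which
  planned-word information is typically decodable. `mixing_mode` draws `A`
  once per participant (`"shared"`: codes generalize across conditions) or
  per condition (`"condition-specific"`: they do not), which is the switch
  behind the across-condition positive and negative controls.
* **Noise.** Per-sensor AR(1) over time (coefficient 0.95, MEG-like
  autocorrelation), spatially correlated through a random covariance with a
  `1/k` eigenvalue spectrum, plus a 30% white component; the total is
  scaled so the signal-to-noise power ratio inside the envelope-active
  window equals `snr` exactly in expectation (realized within 10%).
  There is no physiological noise model to reproduce — this one is simple
  and yields realistic temporal and spatial correlation.
* **Behavior.** Correct responses are Bernoulli(0.98) (observed rates were
  above 97%); speech onsets are Gaussian (sd 80 ms) around the observed
  condition means — adjective 772 ms, noun 792 ms, list 897 ms, phrase
  917 ms — and 940 ms for the unanalysed color-control condition (the
  package's own choice: a two-word utterance, slightly above phrase).
* **Embeddings.** Unit-norm random vectors (`d = 300` by default; smaller
  in examples), optionally blended with a shared component to hit a target
  mean pairwise cosine similarity. Real word2vec-format vectors are
  loadable but never required.

What the generator does *not* emulate: head geometry and leadfields,
eye-blink/cardiac artifacts, inter-participant anatomical variability, or
any systematic semantic structure between categories. Passing tests
therefore certify the *pipeline* — its bookkeeping, estimators, and
statistical calibration — not that real MEG data would yield the original
effect topography.

## Preprocessing details

The band-pass is an order-20 Butterworth, 0.1–40 Hz, applied zero-phase
(forward–backward — phase handling is not documented in the original
description; zero-phase is standard before decoding). A filter of this
order is unusable as a single transfer function, so it is realized as
cascaded second-order sections; with band edges separated by a factor of
400 the band-pass transform itself degenerates numerically, so the cascade
is an order-20 high-pass at 0.1 Hz times an order-20 low-pass at 40 Hz,
whose pole sets coincide with the band-pass transform's to working
precision at this edge ratio. Edge transients are tamed by odd-reflection
padding. Baseline correction subtracts the per-epoch, per-sensor mean over
[−100, 0) ms. Error trials are rejected (no ICA or artifact rejection, as
in the original analysis); when a word's correct-trial count is not a
multiple of the group size, a random seeded subset is dropped (the original
procedure is silent on leftovers).

## Numerical and degenerate-input conventions

* Population (divide-by-N) standard deviations in column normalization;
  zero-variance columns are centered but not scaled.
* Grid values yielding an interpolating fit (`1 − H_ii < 10⁻¹⁰`) get
  infinite LOO error rather than an unstable quotient.
* An all-zero design matrix, non-positive `λ`, `N < 3`, zero-norm vectors
  under cosine distance, unsatisfiable block orderings, and degenerate
  (constant) permutation nulls all raise errors rather than propagate.
* Sample index 0 corresponds to −100 ms; time 0 is picture onset.
* All randomness is seeded; identical seeds give bit-identical schedules,
  embeddings, epochs, splits, and permutations, and package functions
  restore the caller's RNG state.

## Problem sizes

The full-scale geometry (19 participants, 208 sensors, 5 ms grid,
10,000 cluster permutations) is expressed in `default_run_config("full")`
and validated by `run_full(cfg, dry_run = TRUE)` without execution. The
package's own tests and examples run at desk scale — typically 4–30
sensors, reduced sampling rates (250 Hz) or coarse window grids
(25–200 ms), 3 simulated participants, and a few hundred permutations —
sizes chosen so the complete suite exercises every stage, including the
stochastic calibration suites (permutation-null centering; cluster-test
type-I rate over 200 replicates at 500 permutations), in minutes. The
cluster-test calibration draws its no-effect accuracy panels with AR(1)
temporal autocorrelation around chance: heavily overlapping sliding
windows make real accuracy curves smooth, and under time-independent noise
clusters of three adjacent suprathreshold points essentially never form,
which would make the calibration vacuous rather than informative.
Desk-scale accuracies on the high-SNR synthetic data are effectively at
ceiling inside the signal-active window and at chance outside it, which is
the designed behavior, not an empirical claim about MEG.

## Known limitations

* The generator's linear, stationary forward model cannot produce the
  re-emergence/reactivation dynamics that make real TGMs scientifically
  interesting; TGM structure in simulations simply mirrors the envelope.
* The fixed-effects ANOVA treats participants as replicates; no sphericity
  correction is applied (none is documented in the original analysis), and
  inference about effects rests on the within-participant permutation
  scheme rather than the parametric pointwise p-values.
* Epoch-level 0.1 Hz high-pass filtering is edge-dominated in principle
  (the filter's time constant exceeds the epoch); reflection padding keeps
  this benign, but filtering continuous data before epoching would be
  preferable when such data exist.
* `color-control` trials carry two color words and are excluded from
  decoding rather than given an arbitrary label.
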