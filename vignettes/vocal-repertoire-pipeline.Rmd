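---
title: "Mapping a vocal repertoire: features, embedding, clustering and classification"
author: "vocalmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a vocal repertoire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocalmap)
```

## The problem

A vocal repertoire — the set of distinct call types a species produces — is
usually described by a human listener sorting spectrograms into named
categories. That description is hard to compare across studies, and it
glosses over a central biological question: which call types are *discrete*
(acoustically well separated) and which are *graded* (lying on a continuum
without sharp boundaries)? `vocalmap` implements a quantitative pipeline for
this question, modelled on analyses of the indri's repertoire: extract a
fixed spectral feature vector per call, embed the corpus in two dimensions
with t-SNE, cluster the embedding, and measure how well a neural-network
classifier can recover (a) the human type labels and (b) the geometric
cluster labels from the same features. Where the repertoire is graded, the
clusters disagree with the human labels in characteristic ways, and the
type-label classifier's confusions concentrate in the graded pairs.

## The synthetic corpus

No public corpus of labelled indri calls exists, so the package generates
one. The unit is the `call_archetype`: a parametric recipe with a duration
range, a fundamental frequency (f0) range and contour (flat, rising,
falling, or modulated — the last a 5 Hz vibrato of 12% depth for song
units), a harmonic stack (partial amplitudes rolling off as 1/h,
sine-aligned phases), an optional raised-cosine amplitude modulation (the
"pulsed" quality of grunts), an optional band-limited Gaussian noise
component (white noise whose spectrum is zeroed outside the band — a
zero-phase band-pass, chosen so in-band energy expectations are analytic),
and a tonal/noise energy mixing fraction. Calls are peak-normalized to 0.9
full scale and written as 16-bit PCM mono WAV at 44.1 kHz, the format of
the field recordings the generator stands in for.

The ten default archetypes encode the documented qualitative structure, not
measured values — the source analyses publish no per-type acoustic
parameters, so every number in `default_archetypes()` is invented and was
fixed once, before the evaluation suite was finalized, to reproduce the
qualitative pattern (discrete types separate; designated pairs grade):

| type | duration (s) | f0 (Hz) | contour | harmonics | pulse | noise band (Hz) | tonal mix |
|---|---|---|---|---|---|---|---|
| clacson | 0.38–0.46 | 880–940 | falling | 4 | — | — | 0.95 |
| grunt | 0.24–0.30 | 108–133 | flat | 6 | 27 Hz, depth 0.16–0.38 | 80–900 | 0.48–0.68 |
| hum | 0.29–0.33 | 131–148 | flat | 6 | 27 Hz, depth 0.02–0.21 | 80–900 | 0.68–0.82 |
| kiss | 0.10–0.15 | 2310–2600 | falling | 2 | — | 1950–5900 | 0.37–0.60 |
| long tonal | 1.15–1.35 | 280–320 | rising | 5 | — | 250–2500 | 0.75 |
| roar | 0.65–0.80 | 210–240 | flat | 3 | — | 150–2500 | 0.10 |
| short tonal | 0.14–0.20 | 7200–7400 | falling | 1 | — | 6800–8600 | 0.70 |
| wheeze | 0.13–0.18 | 2100–2390 | falling | 2 | — | 1950–5900 | 0.20–0.43 |
| wheezing grunt | 0.35–0.50 | 100–150 | flat | 6 | 24 Hz, depth 0.35–0.50 | 2500–6500 | 0.40–0.50 |
| songbit | 0.6–0.9 | 1600–1700 | modulated | 4 | — | — | 0.95 |

Gradedness is generated by a *shared latent continuum*: for grunt/hum (and
likewise kiss/wheeze) a single latent `u ∈ [0, 1]` is drawn per call and
duration, f0, mix and pulse depth are interpolated from it jointly. Grunts
draw `u` from `[0, 0.60]` and hums from `[0.575, 1]`: the ends of the
continuum are unambiguous, the middle is genuinely mixed. This matters for
two downstream behaviours at once — the joint grunt+hum point cloud is a
single filament rather than two glued blobs, and the type boundary is a
region of irreducible classifier confusion. Kiss/wheeze overlap more broadly
(`[0, 0.58]` vs `[0.42, 1]`), so that pair contributes most of the graded
misclassifications.

Why deterministic (sine-aligned) harmonic phases: with random phases the
crest factor of a harmonic stack varies call to call, and because clips are
peak-normalized, that scale jitter propagates multiplicatively into all 150
band energies, inflating within-type variance with a nuisance factor that
has no acoustic meaning. Deterministic phases keep the peak/RMS ratio
stable within a type; noise realizations still provide natural within-type
variability.

What the generator does **not** emulate: recording-channel effects
(microphone response, distance attenuation, reverberation), background
noise, inter-individual variation, song temporal organization, and any
quantitative fidelity to real indri acoustics. Tests passing on this corpus
show the *pipeline* behaves as designed on data with the assumed structure;
they do not validate the biology.

### Corpus composition

`reference_counts()` records the published per-type sample sizes (3360
calls; grunts alone are 1145). Two corpus designs are available:

- `balanced_counts()` (default of `run_pipeline()`): 30 calls per type, 300
  total. At desk scale this keeps every type's neighborhood structure
  comparable, and the pipeline recovers the repertoire essentially
  perfectly.
- `default_counts()`: the published proportions scaled to one tenth (336
  calls; scaling is round-half-up with the largest class absorbing the
  remainder, so totals are exact). This reproduces the published
  *composition* faithfully — and with it a known behaviour of k-means on
  t-SNE maps: the grunt+hum mass (46% of the corpus) occupies a map area
  proportional to its point count, so the inertia objective splits it
  across several clusters while the rarest types (3–6 calls, far below the
  perplexity of 40) attach as satellites. The result mirrors the published
  cluster table — grunt/hum spread over three mostly-pure clusters,
  kiss/wheeze sharing one, and the three rare chaotic-component types
  (long tonal, roar, short tonal) merged — but partition-recovery scores
  against the merged truth are intrinsically capped near 0.6 in this
  regime. This is a property of the method at these class proportions, not
  an implementation artifact; the balanced design exists precisely to
  separate the two.

## Feature extraction

Each call yields `1 + 10 × 15 = 151` attributes: duration, then band
energies for 10 equal time portions × 15 equal-width bands tiling
[50, 15000) Hz. Choices that needed fixing:

- **Band width.** Fifteen ~996.7 Hz bands follow from requiring 151
  attributes with ten portions; descriptions of similar scripts sometimes
  suggest ~500 Hz bins, which would give 301 attributes instead. The band
  count is configurable (`feature_config(n_bands = )`).
- **Energy definition.** The integral of the one-sided PSD over the band,
  scaled so the integral over [0, Nyquist] equals `Σ x[n]² Δt`
  (amplitude²·seconds). This Parseval convention is unit-consistent and
  analytically checkable (a unit sine of 1 s carries energy 0.5). Absolute
  scale is irrelevant downstream (features are standardized), only relative
  structure matters.
- **Bin assignment.** Rectangular window, no overlap; each DFT bin belongs
  to the band containing its center frequency; bands are half-open `[lo,
  hi)` so adjacent bands never double-count — except that a band whose
  upper edge equals Nyquist also takes the Nyquist bin, so a tiling of
  `[0, Nyquist)` conserves total energy to machine precision rather than
  losing one bin.
- **Portion remainder rule.** When the sample count is not divisible by 10,
  the first `r` portions receive one extra sample; concatenation
  reconstructs the input exactly.
- **Normalization.** Clips are peak-normalized to 0.9 before analysis
  (configurable off), emulating level normalization of field recordings.

## The embedding

The t-SNE implementation is from scratch and split into small, separately
testable operations: squared-distance computation, per-row perplexity
calibration, joint affinities, the Student-t kernel, the KL cost, and exact
and Barnes-Hut gradients.

- **Calibration.** For each point, a binary search on the Gaussian
  precision `beta` targets Shannon entropy `H` (bits) with `2^H` equal to
  the perplexity (default 40), tolerance `1e-5` bits, at most 50
  iterations. Rows of exactly equidistant neighbors (including all-zero
  distances) fall back to the uniform conditional, with a warning for the
  all-zero case. Duplicate feature rows are jittered by `1e-10` before
  distance computation, with a warning.
- **Preprocessing.** Columns are standardized (duration and band energies
  live on wildly different scales), then optionally PCA-reduced to 50
  dimensions — both configurable, defaults chosen to match common practice
  for this embedding.
- **Optimization.** Gaussian initialization (sd 0.01) under the seed; 1000
  iterations at learning rate 200; early exaggeration 12 for the first 250
  iterations (half the run, for short runs); momentum 0.5 switching to 0.8
  when exaggeration ends; per-coordinate adaptive gains (the standard
  0.2/0.8 schedule) on top of momentum. The cost trace is recorded every 50
  iterations, and the run stores the KL at the first post-exaggeration
  iteration so the cost-decrease property is checkable.
- **Barnes-Hut.** For 2-D embeddings and `theta > 0`, the repulsive term is
  approximated with a quadtree (a cell is summarized by its center of mass
  when its extent/distance ratio falls below theta); the attractive term
  uses the affinities exactly, which is exact and affordable at desk scale
  (the corpus is hundreds of calls, so the dense affinity matrix is small).
  `theta = 0` and dimensions other than 2 use the exact gradient. The
  quadtree lives in C++ (Rcpp); the exact gradient is vectorized R, and
  the two are cross-checked against each other and against finite
  differences in the tests.

## Clustering and model selection

Lloyd's algorithm with k-means++ seeding, 10 restarts (best inertia wins)
and a repair rule for clusters emptied during iteration (re-seed with the
point farthest from its current centroid). k is explicit configuration: the
embedding arm uses k = 8, the count suggested by the map's visible clouds
in the emulated analysis; `choose_k()` provides the objective alternative
(maximum mean silhouette width over a k range, ties to the smallest k). The
silhouette uses Euclidean distances and the standard singleton convention
`s(i) = 0`, with 0/0 defined as 0. The comparison arm reduces the raw
features to 6 principal components (`stats::prcomp` behind the package's
interface) and clusters with k = 7. All-identical points with `k ≥ 2` are
rejected — there is no meaningful partition objective.

## Classification

The perceptron follows the conventions of classic machine-learning
workbench implementations: one hidden layer of
`ceiling((n_features + n_classes)/2)` sigmoid units, sigmoid outputs with
one-hot targets and squared-error loss, online (per-instance) updates
`Δw ← −lr · grad + momentum · Δw_prev` with learning rate 0.2 and momentum
0.2 for 500 epochs, per-epoch reshuffling under the seed, inputs
standardized with training-set statistics, and class scores obtained by
dividing the sigmoid outputs by their sum (not softmax). The 67% train
split is stratified by class — the rarest types would otherwise vanish from
train or test entirely — with per-class counts `round(f · n_class)`
adjusted on the largest rounding remainders so the global count is exactly
`round(f · N)`, and at least one train and one test instance per class.

Evaluation mirrors the standard detailed-accuracy table: confusion counts
(true × predicted) and per-true-class percentages (each true class's column
sums to 100), overall accuracy, Cohen's kappa from the marginal products,
MAE and RMSE averaged over instances *and* classes (the per-output error
convention, which is why values like 0.02 arise for 10-class problems),
one-vs-rest TP/FP rates, precision, recall, F-measure and Matthews
correlation per class, ROC areas by trapezoid over unique score thresholds,
PRC areas by interpolation-free step summation, and support-weighted
averages.

One reporting note: single published splits can show different test sizes
for different tasks of the same corpus; this pipeline uses one consistent
stratified split per task configuration, so all three tasks see the same
test size.

## Problem sizes and determinism

The default pipeline synthesizes 300 calls (a minute or two on one CPU,
dominated by the three 500-epoch trainings and the 1000-iteration
embedding); the test suite uses 60–336 call corpora and small random
instances for the oracle checks. Every stage seed derives from the master
seed by a fixed offset, so reruns are byte-identical and stages can be
re-run in isolation. All randomness flows through R's RNG; the generator
saves and restores the caller's RNG state.

## Known limitations

- The archetype parameters are invented; nothing here validates against
  real indri recordings.
- Perplexity 40 at a few hundred points makes classes with fewer than ~10
  members behave as diffuse satellites of their nearest neighbors in
  feature space — visible in the imbalanced corpus, where the three rarest
  types merge. This mirrors the published analysis, where those same three
  types shared a cluster at full scale.
- Praat's band-energy scaling is not reproduced in absolute units; only
  relative structure is used.
- The Barnes-Hut tree is 2-D only; higher output dimensionalities fall back
  to the exact gradient with a warning.
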