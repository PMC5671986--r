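---
title: "Probabilistic EEG microstate analysis: models, parameters and design choices"
author: "microstates package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic EEG microstate analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

EEG microstate analysis treats the instantaneous scalp potential field as
a sequence of quasi-stable global topographies: for roughly 80–120 ms the
spatial *pattern* of the field is approximately constant while its
amplitude oscillates (and may invert in sign), after which the pattern
switches abruptly to another configuration. The analysis therefore has
two distinct objects: a small set of *template maps* (the characteristic
topographies, treated as polarity-invariant) and a per-timepoint *state
label* assigning each EEG sample to one template.

Classically both steps are deterministic: templates come from hard
clustering of the scalp maps at global field power (GFP) peaks, and
labels come from winner-take-all spatial correlation ("backfitting").
This package implements the probabilistic variant of the whole chain:

1. **GFP and peaks.** The GFP at time t is the spatial population
   standard deviation across the C channels,
   GFP(t) = sqrt( (1/C) Σ_i (v_i(t) − v̄(t))² ). It is reference-free;
   its local maxima are the points of highest topographic
   signal-to-noise, and only the maps at those peaks enter template
   estimation. Each peak map is z-normalized across channels so that
   topographies of different amplitude are comparable.
2. **Clustering.** Hard K-means (kmeans++ initialization, Lloyd
   iterations, Euclidean distance) minimizes
   J(X,k) = Σ_i Σ_j ||x_i − c_j||² over assignments; fuzzy C-means (FCM)
   minimizes J(X,m,k) = Σ_i Σ_j U_ij^m ||x_i − c_j||² over a full
   membership matrix U with row sums 1, where the fuzzifier m controls
   how graded the memberships are (m → 1 recovers hard K-means). Both
   are run with replicated random restarts; the replicate with the
   lowest final objective wins.
3. **Polarity merging.** Because a topography and its sign flip are the
   same microstate, plain K-means can return two centroids that are
   near-perfect inversions of each other. Centroid pairs with Pearson
   correlation ≤ −0.95 are merged after clustering (points of the
   removed map are relabeled to the kept map; fuzzy membership columns
   are summed). The silhouette coefficient and the within-cluster
   distance ("elbow") curve are available as model-selection
   diagnostics; the choice of k remains the user's.
4. **Probabilistic labeling.** A softmax multilayer perceptron (one tanh
   hidden layer, default 15 units) is trained by cross-entropy on the
   cluster-labeled peak maps and then applied to *every* timepoint,
   yielding a full probability distribution over microstates per sample
   instead of a binary label. The maximum-likelihood (MLE) label and its
   probability quantify how certain each assignment is.
5. **Uncertainty analyses.** The pooled ECDF of the MLE probability
   describes the certainty profile of a condition; per-subject mean GFP
   and mean MLE probability feed an ordinary least-squares regression
   that quantifies how labeling certainty grows with signal strength.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `clusterConfig(k)` | 5 | number of clusters. With four underlying templates, one of which appears in both polarities, k = 5 lets the clustering isolate both polarities of that map; the polarity merge then returns four templates. |
| `clusterConfig(m)` | 2 | FCM fuzzifier. 2 is the conventional choice; values toward 1 give harder memberships. The pipeline default is 1.8 (see below). |
| `clusterConfig(replicates)` | 10 | random restarts; best final objective wins, ties to the lowest replicate index. |
| `maxIter` | 5000 (KM) / 1000 (FCM) | iteration caps; convergence is normally reached within a few hundred iterations. |
| `clusterConfig(tol)` | 1e-6 | convergence: absolute objective change (KM) or max absolute membership change (FCM). |
| `mergePolarityDuplicates(threshold)` | 0.95 | genuine polarity duplicates correlate near −1; distinct microstate maps correlate far more weakly, so any near-perfect negative pair should merge. |
| `mlpConfig(hiddenUnits)` | 15 | hidden width; ample for k ≤ 9 classes on z-normalized maps. |
| `mlpConfig(maxEpochs)` | 2000 | upper bound; early stopping by validation loss normally ends training after a few hundred epochs. |
| `mlpConfig(splitFractions)` | 0.70/0.15/0.15 | train/validation/test, drawn uniformly at random under the seed. |
| `mlpConfig(patience)` | 6 | consecutive epochs the validation loss may sit above its running minimum before stopping; the best-validation weights are returned. |
| `synthConfig(meanDwell)` | 100 ms | inside the 80–120 ms stability window. |
| `synthConfig(carrierFreq)` | 10 Hz | alpha-band amplitude modulation. |
| `synthConfig(noiseSD)` | 0.6 | sensor noise relative to unit template amplitude; see calibration below. |

## What the synthetic generator emulates — and what it does not

`generateRecording()` produces multichannel EEG whose ground truth is
known exactly: k smooth, mutually decorrelated template topographies
(Gaussian random fields over channel index, orthogonalized and
z-normalized); a first-order Markov state chain with geometric dwell
times floored at 2 samples around a jittered mean dwell; an oscillatory
amplitude envelope |sin(2π f t + φ)| per segment with random phase; and
i.i.d. Gaussian sensor noise. GFP peaks therefore fall near carrier
extrema where topographic SNR is maximal, exactly the regime the
peak-picking step assumes.

**Polarity convention.** Each segment carries the active template with a
segment-level sign, flipped with per-template probability
`inversionProb` (default: 0.5 for the first template, 0.05 for the
rest). This emulates the empirically common situation in which one
topography manifests at GFP peaks with both polarities while the others
are polarity-dominant. The asymmetry is essential, not cosmetic: if every
template appeared equally often with both signs, the sample maps would
form antipodal mode pairs on the z-normalization sphere, and plain
(non-polarity-invariant) K-means would then provably prefer merging
*different* templates over polarity partners — for orthogonal z-normalized
maps, pooling two same-sign templates costs C/2 per point against C for
an antipodal pair — so no clustering of that data could recover the
generative templates. With one polarity-split template the optimal k = 5
solution isolates the five dominant modes, the inverted pair is found at
r ≈ −0.98, and the merge step is load-bearing rather than decorative.

**Calibration of the default conditions.** The noise scale was fixed by
measuring the labeling-certainty profile of trained models across noise
levels: at `noiseSD = 0.6` the mean MLE probability sits near 0.95 with
a meaningful fraction of timepoints below 0.9 certainty — a profile in
which probabilistic labeling is informative rather than saturated — and
certainty varies visibly with subject gain. The two cohort profiles
contrast a "real-movement-like" condition (mean dwell 110 ms, noise 0.5)
with an "imagined-like" condition (mean dwell 70 ms, noise 0.7):
shorter, noisier dwells produce more boundary-mixed maps and lower
assignment certainty, the qualitative condition difference the
uncertainty analyses are designed to expose. Per-subject gains default
to U(0.8, 1.6) in the pipeline cohort; the wider U(0.5, 2) range used
for the 40-subject regression cohort drives a strong positive
GFP-certainty relationship.

What the generator does **not** emulate: electrode geometry (smoothness
is over channel index, not scalp distance, so no topographic plotting is
meaningful), ocular/muscular artifacts, 1/f background spectra,
inter-subject template variability, and volume-conduction mixing of
simultaneously active sources. Passing tests on this data therefore
demonstrate the correctness and internal consistency of the algorithms
under the stated generative assumptions — not that real EEG satisfies
those assumptions.

## Numerical choices

- **GFP** uses the population (divide-by-C) standard deviation, the
  conventional definition. **Map z-normalization** uses the sample
  (divide-by-(C−1)) standard deviation, matching `scale()`; the same
  rule is applied identically at training and prediction time, so the
  distinction never crosses the two contexts.
- **Peak plateaus:** a run of equal GFP values flanked by strictly
  smaller neighbours contributes its first index; series endpoints are
  never peaks.
- **Degenerate maps:** zero-spatial-variance timepoints cannot be
  z-normalized; they are dropped (with a warning) from peak extraction,
  given the uniform probability row and excluded from certainty
  summaries at prediction, and left unlabeled (NA) by backfitting.
- **Empty K-means clusters** are repaired by reseeding the empty
  centroid to the point farthest from its assigned centroid and moving
  that point, which cannot empty another cluster.
- **FCM zero distances:** a point coinciding with one or more centroids
  splits membership 1 equally among the coinciding centroids. At small
  m − 1 the membership update normalizes by the row-minimum distance
  before exponentiation to avoid overflow.
- **Ties** always break to the lowest index: replicate ties on the
  objective, MLE label ties, backfit correlation ties.
- **Label alignment** between template sets maximizes total absolute
  correlation over one-to-one assignments with an exact branch-and-bound
  search (equivalent to exhaustive enumeration, fast for the k used
  here); greedy sorting can be order-dependent, so it is not used.
- **MLP optimization** is full-batch scaled conjugate gradients (one
  epoch = one SCG step), with a backtracking-line-search gradient
  descent available as `optimizer = "gdls"`; both minimize the same
  cross-entropy, and results depend on the loss reached, not the
  optimizer. Weights initialize uniformly scaled by 1/sqrt(fan-in)
  under the seed.
- **Reproducibility:** every function takes its randomness from an
  explicit seed and restores the caller's RNG state; the pipeline
  derives all stage seeds from one root seed, and stage outputs are
  content-addressed by a hash of the stage configuration plus its
  upstream hashes, so a rerun with one changed downstream setting
  reuses cached upstream results, and identical configurations
  reproduce byte-identical artifacts.

## The pipeline fuzzifier (m = 1.8)

`clusterConfig()` defaults to the conventional m = 2, and that is the
right general-purpose setting. The pipeline's default clustering uses
m = 1.8 for a specific reason: with k one larger than the number of
underlying templates and one template present in both polarities, the
fuzzy objective at m = 2 develops a competing "grand-mean" optimum on
noisy cohorts — distant points retain enough membership that a centroid
parked near the origin collects them, absorbing the polarity-split
cluster instead of resolving it. Sharpening the memberships slightly
(m = 1.8) removes that attractor across the noise levels the cohort
profiles use while keeping memberships genuinely graded (typical winning
memberships ~0.7–0.95, not one-hot). Users clustering their own data at
k close to the true number of states can keep m = 2.

## Problem sizes in the shipped tests

The test suite exercises the full pipeline on an 8-subject, 2-condition
cohort of 20 s recordings at 160 Hz with 64 channels (~4000 peak maps
per condition), and the subject-level regression on a 40-subject,
32-channel cohort of 6 s recordings; oracle comparisons (exhaustive
partition enumeration, double-loop silhouette, 24-permutation
alignment) run on deliberately small inputs where exhaustive computation
is exact. These sizes were chosen so the whole suite completes in well
under a minute while every stage still operates in its intended regime.

## Known limitations

- Template alignment requires equal k on both sides; models that merge
  to different template counts are reported unaligned by the pipeline
  rather than force-matched.
- The deterministic backfit assigns every finite-variance timepoint a
  label, however weak the winning correlation; no correlation floor is
  imposed (none is standard).
- FCM with k well above the true number of states on very noisy data can
  still place a centroid on noise; the recovery report (`scoreRecovery`)
  makes this visible rather than hiding it.
- Microstate transition dynamics (dwell statistics on real data,
  transition matrices) are out of scope.
- The EDF reader supports the common continuous EDF/EDF+ signal layout
  (uniform sampling rate across signal channels, 16-bit records);
  discontinuous EDF+D files are not supported.
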