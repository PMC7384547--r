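---
title: "Curating CNMF-E ROIs with roicurate: models, simulation and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating CNMF-E ROIs with roicurate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roicurate)
```

## The curation problem

Source extraction for 1-photon miniscope calcium imaging — typically CNMF-E —
returns, for each putative neuron, a *spatial footprint* (the cell's pixel
weights in the field of view) and a *calcium trace* (its inferred fluorescence
over time). Source extraction is imperfect: some returned regions of interest
(ROIs) are background blobs, merged cell pairs, or traces of non-neuronal
origin. Before downstream analysis, each ROI is therefore curated:
**include** (a real neuron) or **exclude** (an artifact). Done by eye across
tens of thousands of ROIs, this is slow and not perfectly reproducible —
two trained raters typically agree on only ~85–90% of borderline cases.

`roicurate` treats curation as supervised classification. A classifier is
trained on a modest set of human-labeled ROIs and applied to the rest; its
per-ROI confidence then drives a triage policy in which only low-confidence
calls return to a human. The package covers the full loop: reading CNMF-E
output, featurization, training and cross-validation, confidence triage,
evaluation, and a synthetic benchmark with known ground truth.

## From ROI to feature vector

Curators judge a footprint by its shape and size, not by where it sits in
the field of view, and judge a trace by its dynamics, not by its absolute
scale. The featurization encodes exactly that:

* **Footprint crop.** An 80 × 80 px window centered on the footprint's peak
  pixel (ties broken by smallest row, then column — deterministic and
  order-independent). Window regions outside the FOV are zero-filled; the
  peak lands at 0-based position (40, 40). This removes location information
  and empty space while preserving shape, size and brightness.
* **Trace crop + normalization.** The first 500 frames (100 s at the 5 Hz
  default frame rate) are kept; shorter recordings are zero-padded at the
  end rather than discarded, so variable-length sessions keep their ROIs.
  Each trace is min-max normalized to [0, 1]; a constant trace maps to all
  zeros. Per-trace min-max is the conventional choice for batches of traces
  of mixed absolute scale, and `trace_norm = "none"` is available where raw
  amplitudes matter.
* **Flatten and concatenate.** The crop is flattened row-major (pixel
  (y, x) at position y·width + x) and the trace appended: 6,400 + 500 =
  6,900 features per ROI. Spatial-only and trace-only variants are column
  blocks of the same vector, which is how the modality comparison below is
  run.

Train/test splits are stratified per class (`round(test_fraction * n_class)`
test members per class, so test proportions match the dataset within one
sample per class) and are a pure function of the seed.

## Classifiers, cross-validation and triage

Two conventional families are built in, deliberately close to their
out-of-the-box configurations:

* **Decision tree** (`rpart`): unpruned (`cp = 0`), minimum leaf size 1,
  depth limit 30. Confidence is the leaf's class fraction.
* **K-nearest neighbours** (`class::knn`): k = 5. Confidence is the
  neighbour vote fraction for the winning class.

Both accept an optional PCA step (50 components by default) fitted on
training rows only; test rows never influence fitted state, and the test
suite asserts this by perturbing test rows and comparing fitted parameters.
An `external_automl` family defines the plug-in contract (`fit(x, y)` /
`predict(model, x)`) under which a heavier external engine — e.g. an AutoML
search producing a scikit-learn ensemble — can stand behind the same
interface; no such search ships with the package.

Model selection uses stratified 10-fold cross-validation (folds preserve the
include/exclude mix to within one sample), optimizing F1 on the positive
(*include*) class — the harmonic mean of precision and recall. Repeated CV
pools all fold scores. When false positives and false negatives are not
equally costly (a few highly active false-positive ROIs can distort
downstream statistics more than the loss of a few true cells), the F-beta
objective exposes the trade-off: beta > 1 weights recall, beta < 1 weights
precision.

Triage is a single threshold on confidence: predictions at or above
`auto_threshold` (default 0.9) are routed automatically, the rest are queued
for review. The threshold must exceed 0.5 (below that, a two-class
confidence cannot be the argmax class's), and the review queue is monotone
in the threshold.

## The synthetic ground-truth generator

Real labeled recordings are lab-internal, so the package ships a generator
whose defaults define the benchmark conditions used throughout the tests:

* 2,000 ROIs on an 80 × 80 px FOV, 500 frames at 5 Hz.
* **Positives** emulate the visual inclusion criteria: an anisotropic
  Gaussian footprint (radius ≈ 4 px, random center/orientation/amplitude,
  thresholded to zero below 10⁻³ of peak, since extracted footprints are
  sparse), and a trace with a stable baseline plus transients at 0.01
  events/frame (one per 20 s) convolved with a double-exponential kernel
  (2-frame rise, 10-frame decay — GCaMP6f-like at 5 Hz), plus small
  observation noise.
* **Negatives**: 15% of ROIs — the class imbalance of typical curated 1p
  datasets — corrupted by one of four modes (uniform weights): `spatial`
  (footprint rescaled about its peak by a factor from {1/3, 1/2, 2, 3},
  bilinear resampling), `trace` (Gaussian noise at 2 × the trace sd, enough
  to visibly destroy the stable baseline while staying in a realistic
  range), `both`, or `merged` (pixelwise/framewise sum with a sacrificial
  partner ROI; sum rather than mean because the source-extraction model is
  additive, with mean available).

Everything is a pure function of the seed; identical seeds reproduce
bit-identical collections. A 2p-to-1p emulation step (`emulate_1p`) performs
block/bin averaging for workflows that start from higher-resolution data.

What the generator does *not* emulate: correlated background fluorescence,
neuropil contamination, motion artifacts, overlapping footprints beyond the
merged mode, and the genuinely ambiguous "edge cases" on which even human
raters disagree. Synthetic negatives are drawn from cleanly parameterized
corruption families, so classifiers separate them more easily than real
artifacts: a green test here demonstrates that the pipeline's mechanics are
correct and that the corruption modes are learnable, not that any given F1
will transfer to a particular lab's recordings.

```{r example, eval = FALSE}
gt <- make_simulated_ground_truth(sim_spec(n_rois = 500, seed = 1))
ds <- assemble_dataset(gt$collection, preprocess_spec(), 0.2, seed = 1)
bundle <- train_classifier(ds, classifier_spec("knn", cv_folds = 10, seed = 1))
pred <- predict(bundle, ds$features[ds$split == "test", ])
confusion(ds$labels[ds$split == "test"], pred$label)
```

## Evaluation surfaces

* **Confusion matrices** are reported as counts and as row-normalized
  proportions (per true class), the form used in curation figures.
* **Interrater agreement** is the fraction of identically labeled ROIs
  between two raters, with the rater-vs-rater table alongside.
* **Cohen's d of confidence** quantifies whether the classifier is less
  certain on its mistakes: for predicted-include ROIs, d between the
  confidences of true and false positives; likewise for predicted-exclude.
  d uses the pooled-sd form with n − 1 variances; groups with fewer than
  two members yield an undefined marker rather than an error. Large positive
  d is what makes confidence triage work: errors concentrate below the
  threshold.
* **Learning curves** re-fit the pipeline on stratified subsamples of
  increasing size (nested by default — each size's sample contains the
  previous one, reducing curve variance; independent draws are available)
  against a fixed test set, answering "how many labeled ROIs are enough?".

### Change-point detection

The plateau of a learning curve is located with PELT (Pruned Exact Linear
Time) under the Gaussian mean-shift cost: segments are scored by the sum of
squared deviations from the segment mean, plus a penalty per change point.
PELT's pruning removes only provably suboptimal candidates, so its output is
the exact optimum — the test suite checks it against exhaustive enumeration
of all segmentations on short series. Choices that were genuinely open:

* **Penalty default** `2·log(n)·var(series)`: the var term makes the
  penalty scale-free (rescaling the scores rescales cost and penalty alike);
  the log(n) factor is the usual BIC-flavored default. Any positive penalty
  can be passed instead; a non-positive penalty is an error (at penalty 0
  every point becomes a change point).
* **Indexing**: change points are reported as 1-based indices of the first
  element of each new segment — `c(0, 0, 0, 1, 1, 1)` yields 4 — matching R
  convention.
* **Plateau summary**: the largest detected change-point location is
  reported as `plateau_size`, alongside the full set.
* **Ties** in the optimal cost are broken toward the earliest admissible
  previous segment end, making results deterministic.

A curve that is still rising at the top of the size budget has no plateau to
find, and PELT correctly returns no change point for it. On the synthetic
benchmark this is the behaviour of the unpruned tree (which keeps improving
through 1,600 samples), whereas the KNN baseline saturates within the first
few hundred ROIs; the bundled plateau checks therefore analyze the KNN
curve.

## Numerical and degenerate-input conventions

* All-zero footprints are loaded and *flagged*, never silently dropped;
  only explicit downstream steps remove ROIs. Cropping an all-zero
  footprint is a degenerate-input error.
* Precision/recall with empty denominators return 0 with a `degenerate`
  attribute rather than NaN, so scores stay comparable inside CV loops.
* Constant traces min-max to all zeros; corrupting a constant trace falls
  back to an absolute noise floor and records that fact.
* HDF5 orientation (pixels × K vs K × pixels, K × T vs T × K) is resolved
  by matching the shared ROI count K across the two matrices; layouts that
  remain ambiguous (square matrices) require an explicit flag instead of a
  guess. R- and Python-written containers therefore load identically.
* Every stochastic step (simulation, splits, folds, subsampling) flows from
  an explicit integer seed through an isolated RNG scope, so results are
  reproducible without disturbing the caller's RNG state.

## Problem sizes used in the checks

The bundled checks run the benchmark at 2,000 ROIs with the full 6,900-dim
featurization (the corruption-bookkeeping check additionally generates 7,200
ROIs to verify exact negative counts at scale, 1,080 = 15% of 7,200), with
learning-curve sizes 50–1,600. Unit tests use a 32 × 32 px / 120-frame
geometry, which exercises identical code paths at a fraction of the cost.

## Known limitations

* The decision tree and KNN baselines are intentionally plain; the package's
  contribution is the pipeline and evaluation machinery, and stronger models
  are expected to arrive through the external-engine seam.
* KNN bundles store their training matrix (the model *is* the data), so
  bundle files scale with the training set.
* Pre-7.3 MAT files are not HDF5 and are rejected with advice to re-save;
  cross-session registration, motion correction and raw-movie I/O are out of
  scope.
* Synthetic benchmarks overstate separability relative to real recordings
  (see above); for production use, train on your own labeled ROIs and
  validate the triage threshold against a held-out human-labeled set.
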