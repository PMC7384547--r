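# roicurate

Semi-automated curation of ROIs extracted from 1-photon calcium imaging by
CNMF-E (constrained non-negative matrix factorization for microendoscopic
data).

## The problem

Source extraction for miniscope recordings returns, per putative neuron, a
spatial footprint **a** (pixel weights over the field of view) and a calcium
trace **c** (inferred fluorescence over frames). A fraction of these ROIs
are artifacts — background blobs, merged cell pairs, unstable traces — and
must be curated (*include* vs *exclude*) before analysis. Visual inspection
of 10⁴–10⁵ ROIs is slow and imperfectly reproducible; `roicurate` turns the
curated subset you already have into a classifier and routes only
low-confidence calls back to a human.

## The method

Each ROI is mapped to a fixed-length feature vector

```
x = [ vec(crop80(a)) , minmax(c[1:500]) ]  ∈  R^(6400 + 500)
```

an 80 × 80 px crop centered on the footprint peak (row-major flattened)
concatenated with the first 500 frames of the trace, min-max normalized to
[0, 1]. Include/exclude classifiers — decision tree, k-nearest neighbours
(k = 5), optionally preceded by PCA — are selected by stratified 10-fold
cross-validation maximizing

```
F_beta = (1 + beta^2) P R / (beta^2 P + R),   P = tp/(tp+fp),  R = tp/(tp+fn)
```

with beta = 1 (F1) by default and the *include* class as positive.
Per-ROI confidence (leaf class fraction for trees, neighbour vote fraction
for KNN) feeds a triage policy: predictions with confidence ≥ threshold are
auto-routed, the rest go to a review queue.

Evaluation tools cover proportion confusion matrices, precision/recall/
F-beta, interrater agreement, Cohen's d between confidences of correct and
incorrect predictions (pooled-sd form), and learning curves with exact PELT
change-point detection (Gaussian mean-shift cost) to find the labeled-data
budget at which performance plateaus.

Because labeled recordings are lab-internal, the package ships a synthetic
benchmark: positive ROIs (compact Gaussian footprints; fast-rise/slow-decay
transients on a stable baseline) with 15% corrupted into negatives by four
modes — footprint rescaling by {1/3, 1/2, 2, 3}, trace noise at 2 × sd,
both, or merging two ROIs into one.

## Worked example

```r
library(roicurate)

gt <- make_simulated_ground_truth(
  sim_spec(n_rois = 300, fov = fov_geometry(48, 48, 200),
           footprint_radius = 3, seed = 1))
ds <- assemble_dataset(gt$collection,
                       preprocess_spec(crop_size = 32, trace_len = 200),
                       test_fraction = 0.2, seed = 1)
bundle <- train_classifier(ds, classifier_spec("decision_tree",
                                               cv_folds = 5, seed = 1))
bundle$cv_report
#> <cv_report> F1 = 0.9017 +/- 0.0126 (5 folds x 1 repeats)

te <- ds$split == "test"
pred <- predict(bundle, ds$features[te, ])
confusion(ds$labels[te], pred$label)
#> <confusion> n = 60 (tp 47, fp 2, fn 4, tn 7)
#>         include exclude
#> include   0.922   0.078
#> exclude   0.222   0.778
```

Cross-validated F1 is 0.90; on the held-out 60 ROIs the tree recovers 92%
of true cells and 78% of artifacts (rows of the matrix are proportions per
true class). With the KNN family, confidence triage partitions the same
test set so that only uncertain calls need a human:

```r
tri <- triage(predict(train_classifier(ds, classifier_spec("knn", cv_folds = 5, seed = 1)),
                      ds$features[te, ]),
              triage_policy(0.9))
#> auto-included 45, auto-excluded 1, queued for review 14
```

The same pipeline is scriptable from a shell via the installed CLI
(`system.file("cli", "roicurate", package = "roicurate")`) with subcommands
`simulate`, `prepare`, `train`, `predict`, `evaluate`, `learning-curve`;
real CNMF-E output is read from HDF5/MAT v7.3 containers with
`load_cnmfe_output()` and labels from `id,label` CSVs.

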