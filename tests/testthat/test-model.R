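# hand-built dataset helpers ------------------------------------------------

# perfectly separable two-cluster dataset wrapped as an roi_dataset
separable_dataset <- function(n = 60, d = 8, gap = 10, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("include", "exclude"), c(round(0.7 * n), n - round(0.7 * n))),
              levels = c("exclude", "include"))
  x <- matrix(rnorm(n * d), n, d)
  x[y == "exclude", 1] <- x[y == "exclude", 1] + gap
  ids <- sprintf("r%03d", seq_len(n))
  rownames(x) <- ids
  split <- rep("train", n)
  split[seq(1, n, by = 5)] <- "test"
  structure(list(features = x, labels = y, ids = ids, split = split,
                 provenance = rep("synthetic", n),
                 spec = preprocess_spec(2, 4)),
            class = "roi_dataset")
}

test_that("cross-validation is stratified, deterministic, and exact on separable data", {
  ds <- separable_dataset()
  spec <- classifier_spec("decision_tree", cv_folds = 5, seed = 3)
  cv <- cross_validate(ds, spec)
  expect_length(cv$scores, 5)
  expect_equal(cv$scores, rep(1, 5))
  cv2 <- cross_validate(ds, spec)
  expect_identical(cv$scores, cv2$scores)
  # fold stratification: minority proportion within one sample of global
  tr <- which(ds$split == "train")
  y <- ds$labels[tr]
  folds <- withr::with_seed(3, caret::createFolds(y, k = 5))
  p_global <- mean(y == "exclude")
  for (f in folds) {
    expect_lte(abs(mean(y[f] == "exclude") - p_global), 1 / length(f))
  }
  # repeats pool scores
  cv3 <- cross_validate(ds, classifier_spec("knn", cv_folds = 4, cv_repeats = 3,
                                            seed = 1))
  expect_length(cv3$scores, 12)
})

test_that("cross-validation errors when a class cannot fill the folds", {
  ds <- separable_dataset(n = 40)
  ds$labels <- factor(rep("include", 40), levels = c("exclude", "include"))
  expect_error(cross_validate(ds, classifier_spec("knn")), "both classes")
  ds2 <- separable_dataset(n = 30)
  expect_error(cross_validate(ds2, classifier_spec("knn", cv_folds = 10)),
               "stratification")
})

test_that("shuffled labels score at the permutation-null level", {
  ds <- separable_dataset(n = 80, gap = 0, seed = 5)  # pure noise features
  set.seed(11)
  ds$labels <- factor(sample(rep(c("include", "exclude"), c(68, 12))),
                      levels = c("exclude", "include"))
  cv <- cross_validate(ds, classifier_spec("knn", cv_folds = 5, seed = 2))
  # chance band: brute-force label-shuffling null (random pairings at the
  # same class mix) up to the no-information majority-class baseline, which
  # is the other way a classifier can behave without signal
  y <- ds$labels[ds$split == "train"]
  null <- replicate(200, {
    unname(prf_scores(confusion(y, sample(y)))["f_beta"])
  })
  majority <- unname(prf_scores(confusion(y, rep("include", length(y))))["f_beta"])
  expect_gte(cv$mean, min(null) - 0.1)
  expect_lte(cv$mean, max(c(null, majority)) + 0.02)
  # and far below what the same family reaches on informative labels
  informative <- cross_validate(separable_dataset(n = 80, gap = 10, seed = 5),
                                classifier_spec("knn", cv_folds = 5, seed = 2))
  expect_gt(informative$mean, max(null) + 0.02)
})

test_that("training records CV, respects PCA dimensions, and is reproducible", {
  ds <- separable_dataset()
  spec <- classifier_spec("decision_tree", use_pca = TRUE, n_components = 5,
                          cv_folds = 4, seed = 9)
  b <- train_classifier(ds, spec)
  expect_s3_class(b, "classifier_bundle")
  expect_equal(b$feature_dim, 5L)
  expect_equal(b$input_dim, 8L)
  expect_s3_class(b$cv_report, "cv_report")
  # train-set predictions on separable data are perfect
  pred <- predict(b, ds$features[ds$split == "train", , drop = FALSE])
  cm <- confusion(ds$labels[ds$split == "train"], pred$label)
  expect_equal(unname(prf_scores(cm)["f_beta"]), 1)
  # serialization determinism (timestamp aside, bundles are byte-identical)
  b2 <- train_classifier(ds, spec)
  strip <- function(x) serialize(x[setdiff(names(x), "created")], NULL)
  expect_identical(strip(unclass(b)), strip(unclass(b2)))
})

test_that("PCA is fitted on training rows only (no test leakage)", {
  ds <- separable_dataset(n = 60, seed = 2)
  spec <- classifier_spec("knn", use_pca = TRUE, n_components = 4, cv_folds = 3)
  b1 <- train_classifier(ds, spec, run_cv = FALSE)
  # perturb the test rows wildly; fitted state must not change
  ds2 <- ds
  ds2$features[ds2$split == "test", ] <- 1e6
  b2 <- train_classifier(ds2, spec, run_cv = FALSE)
  expect_identical(b1$fit$pca, b2$fit$pca)
  expect_identical(b1$fit$core, b2$fit$core)
})

test_that("KNN confidences are neighbour vote fractions", {
  x <- matrix(c(0, 0.1, 0.2, 5), ncol = 1)
  rownames(x) <- paste0("r", 1:4)
  y <- factor(c("include", "include", "exclude", "include"),
              levels = c("exclude", "include"))
  ds <- structure(list(features = x, labels = y, ids = rownames(x),
                       split = rep("train", 4), provenance = rep("", 4),
                       spec = preprocess_spec(1, 1)),
                  class = "roi_dataset")
  # k = 3 around 0: neighbours r1,r2 (include), r3 (exclude) -> 2/3 include
  b <- train_classifier(ds, classifier_spec("knn", hyperparameters = list(k = 3)),
                        run_cv = FALSE)
  p <- predict(b, matrix(0, 1, 1))
  expect_equal(p$label, "include")
  expect_equal(p$confidence, 2 / 3)
  # k = 1 on a training exemplar: that label with confidence 1
  b1 <- train_classifier(ds, classifier_spec("knn", hyperparameters = list(k = 1)),
                         run_cv = FALSE)
  p1 <- predict(b1, x[3, , drop = FALSE])
  expect_equal(p1$label, "exclude")
  expect_equal(p1$confidence, 1)
  # empty input -> empty output
  p0 <- predict(b1, x[0, , drop = FALSE])
  expect_equal(nrow(p0), 0L)
  # two-class confidences never drop below 0.5
  ds_big <- separable_dataset(n = 50, gap = 1, seed = 8)
  bb <- train_classifier(ds_big, classifier_spec("knn"), run_cv = FALSE)
  pp <- predict(bb, ds_big$features)
  expect_true(all(pp$confidence >= 0.5))
})

test_that("prediction accepts raw ROIs via the stored preprocessing recipe", {
  ds <- tiny_dataset(n_rois = 40, seed = 15)
  b <- train_classifier(ds, classifier_spec("decision_tree", cv_folds = 3),
                        run_cv = FALSE)
  gt <- make_simulated_ground_truth(tiny_sim_spec(n_rois = 5, seed = 16))
  p_col <- predict(b, gt$collection)
  expect_equal(nrow(p_col), 5L)
  expect_identical(p_col$roi_id, gt$collection$ids)
  p_one <- predict(b, get_roi(gt$collection, 2))
  expect_identical(p_one$label, p_col$label[2])
  expect_error(predict(b, matrix(0, 2, 7)), "dimension mismatch.*356.*7")
})

test_that("triage partitions by confidence and is monotone in the threshold", {
  pred <- data.frame(roi_id = sprintf("r%02d", 1:10),
                     label = rep(c("include", "exclude"), 5),
                     confidence = c(rep(0.55, 4), rep(0.95, 6)))
  tri <- triage(pred, triage_policy(0.9))
  expect_equal(nrow(tri$review_queue), 4L)
  expect_equal(nrow(tri$auto_include) + nrow(tri$auto_exclude), 6L)
  expect_identical(tri$review_queue$roi_id, pred$roi_id[1:4])  # order kept
  # all-but-perfect threshold queues everything below 1
  tri1 <- triage(pred, triage_policy(1.0))
  expect_equal(nrow(tri1$review_queue), 10L)
  # monotonicity: raising the threshold never shrinks the queue
  thresholds <- c(0.6, 0.7, 0.9, 0.96, 1.0)
  sizes <- vapply(thresholds,
                  function(th) nrow(triage(pred, triage_policy(th))$review_queue),
                  numeric(1))
  expect_true(all(diff(sizes) >= 0))
  expect_error(triage_policy(0.5), "auto_threshold")
})

test_that("bundles persist and reload with identical predictions", {
  ds <- separable_dataset(n = 50, seed = 4)
  b <- train_classifier(ds, classifier_spec("knn"), run_cv = FALSE)
  path <- withr::local_tempfile(fileext = ".rds")
  save_bundle(b, path)
  b2 <- load_bundle(path)
  expect_identical(predict(b2, ds$features), predict(b, ds$features))
  expect_identical(b2$spec, b$spec)
  expect_identical(b2$cv_report, b$cv_report)
  # truncated archives and foreign RDS files are rejected
  raw_bytes <- readBin(path, "raw", file.info(path)$size)
  writeBin(raw_bytes[1:20], path)
  expect_error(load_bundle(path), "not a readable bundle|incompatible")
  saveRDS(list(a = 1), path)
  expect_error(load_bundle(path), "incompatible bundle format")
})

test_that("the external family is a contract seam, not an engine", {
  ds <- separable_dataset(n = 40)
  expect_error(train_classifier(ds, classifier_spec("external_automl"),
                                run_cv = FALSE),
               "plug-in seam")
  # honouring the contract plugs straight in: a trivial majority-class engine
  eng <- classifier_spec("external_automl", hyperparameters = list(
    fit = function(x, y) names(which.max(table(y))),
    predict = function(model, x) list(label = rep(model, nrow(x)),
                                      confidence = rep(1, nrow(x)))
  ))
  b <- train_classifier(ds, eng, run_cv = FALSE)
  p <- predict(b, ds$features[1:3, , drop = FALSE])
  expect_equal(p$label, rep("include", 3))
})
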