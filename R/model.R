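#' Specification of an include/exclude classifier pipeline
#'
#' Describes a classifier over ROI feature vectors: the model family
#' (decision tree, k-nearest neighbours, or an externally supplied engine),
#' an optional PCA step fitted on training rows only, the optimization
#' objective (F1, or F-beta for asymmetric precision/recall weighting), and
#' the stratified cross-validation layout.
#'
#' @param family `"decision_tree"`, `"knn"`, or `"external_automl"`. The
#'   external family is a plug-in seam: supply `fit(x, y)` and
#'   `predict(model, x)` functions through `hyperparameters`; no AutoML
#'   search ships with this package.
#' @param use_pca Whether to apply PCA before the classifier.
#' @param n_components Number of principal components kept when `use_pca`.
#' @param hyperparameters Named list. Recognized: `k` (KNN neighbour count,
#'   default 5), `minsplit`/`minbucket`/`cp`/`maxdepth` (decision tree;
#'   defaults 2/1/0/30, i.e. an unpruned tree with minimum leaf size 1),
#'   `fit`/`predict` (external family).
#' @param objective `"f1"` (default) or `"f_beta"`.
#' @param beta Positive recall weight used when `objective = "f_beta"`.
#' @param cv_folds Number of stratified folds (default 10).
#' @param cv_repeats Number of CV repetitions; fold scores are pooled.
#' @param seed Integer seed controlling fold assignment.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("decision_tree", "knn", "external_automl"),
                            use_pca = FALSE, n_components = 50L,
                            hyperparameters = list(),
                            objective = c("f1", "f_beta"), beta = 1,
                            cv_folds = 10L, cv_repeats = 1L, seed = 1L) {
  family <- match.arg(family)
  objective <- match.arg(objective)
  cv_folds <- as.integer(cv_folds)
  if (cv_folds < 2L) stop("classifier_spec: cv_folds must be >= 2")
  if (beta <= 0) stop("classifier_spec: beta must be > 0")
  structure(
    list(family = family, use_pca = isTRUE(use_pca),
         n_components = as.integer(n_components),
         hyperparameters = hyperparameters, objective = objective,
         beta = as.numeric(beta), cv_folds = cv_folds,
         cv_repeats = as.integer(cv_repeats), seed = as.integer(seed)),
    class = "classifier_spec"
  )
}

objective_beta <- function(spec) if (spec$objective == "f1") 1 else spec$beta

hp <- function(spec, name, default) {
  v <- spec$hyperparameters[[name]]
  if (is.null(v)) default else v
}

# Fit the (optional PCA +) classifier core on a feature matrix. All fitted
# state (PCA center/rotation included) derives from x/y only.
fit_classifier_core <- function(x, y, spec) {
  stopifnot(is.matrix(x), is.factor(y))
  input_dim <- ncol(x)
  pca <- NULL
  if (spec$use_pca) {
    nc <- min(spec$n_components, ncol(x), nrow(x) - 1L)
    p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = nc)
    pca <- list(center = p$center, rotation = p$rotation)
    x <- p$x
  }
  core <- switch(
    spec$family,
    decision_tree = {
      df <- as.data.frame(x)
      colnames(df) <- paste0("f", seq_len(ncol(x)))
      df$.label <- y
      fit <- rpart::rpart(
        .label ~ ., data = df, method = "class",
        control = rpart::rpart.control(
          minsplit = hp(spec, "minsplit", 2L),
          minbucket = hp(spec, "minbucket", 1L),
          cp = hp(spec, "cp", 0),
          maxdepth = hp(spec, "maxdepth", 30L),
          xval = 0L
        )
      )
      # drop references to the fitting environment so bundles serialize
      # compactly and reproducibly
      attr(fit$terms, ".Environment") <- globalenv()
      fit$call <- quote(rpart::rpart())
      fit
    },
    knn = list(x = x, y = y, k = as.integer(hp(spec, "k", 5L))),
    external_automl = {
      fit_fun <- hp(spec, "fit", NULL)
      if (!is.function(fit_fun) || !is.function(hp(spec, "predict", NULL))) {
        stop("external_automl is a plug-in seam: supply hyperparameters$fit(x, y) ",
             "and hyperparameters$predict(model, x) functions honouring the ",
             "dataset-in / predictions-out contract")
      }
      fit_fun(x, y)
    }
  )
  list(family = spec$family, pca = pca, core = core,
       input_dim = input_dim, model_dim = ncol(x), spec = spec)
}

# Predict labels + confidences from a fitted core. Confidence is the
# probability assigned to the predicted class: leaf class fraction for trees,
# neighbour vote fraction for KNN.
predict_classifier_core <- function(fit, x) {
  stopifnot(is.matrix(x))
  if (ncol(x) != fit$input_dim) {
    stop(sprintf("predict: feature dimension mismatch: model expects %d, input has %d",
                 fit$input_dim, ncol(x)))
  }
  if (nrow(x) == 0L) {
    return(data.frame(label = character(0), confidence = numeric(0)))
  }
  if (!is.null(fit$pca)) {
    x <- sweep(x, 2, fit$pca$center) %*% fit$pca$rotation
  }
  switch(
    fit$family,
    decision_tree = {
      df <- as.data.frame(x)
      colnames(df) <- paste0("f", seq_len(ncol(x)))
      p <- stats::predict(fit$core, df, type = "prob")
      lab <- colnames(p)[max.col(p, ties.method = "first")]
      data.frame(label = lab, confidence = p[cbind(seq_len(nrow(p)),
                                                   max.col(p, ties.method = "first"))])
    },
    knn = {
      cl <- class::knn(fit$core$x, x, fit$core$y, k = fit$core$k, prob = TRUE)
      data.frame(label = as.character(cl), confidence = attr(cl, "prob"))
    },
    external_automl = {
      out <- fit$spec$hyperparameters$predict(fit$core, x)
      data.frame(label = as.character(out$label),
                 confidence = as.numeric(out$confidence))
    }
  )
}

check_cv_feasible <- function(y, spec) {
  tab <- table(y)
  if (length(tab) < 2L || any(tab == 0L)) {
    stop("cross_validate: both classes must be present in the training rows")
  }
  if (any(tab < spec$cv_folds)) {
    stop("cross_validate: stratification error: class counts (",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
         ") below cv_folds = ", spec$cv_folds)
  }
}

#' Stratified repeated cross-validation of a classifier spec
#'
#' Scores the spec with stratified k-fold cross-validation on the training
#' rows of the dataset: folds preserve the include/exclude proportions (each
#' fold's class proportions are within one sample of the global ones), the
#' objective (F1 or F-beta, positive class = include) is computed per fold,
#' and repeats are pooled. Fold assignment is a deterministic function of the
#' spec's seed.
#'
#' @param dataset An `roi_dataset` (its `"train"` rows are used).
#' @param spec A [classifier_spec()].
#' @return An object of class `cv_report`: list with `scores` (length
#'   `cv_folds * cv_repeats`), `mean`, `sd`, `objective`, `beta`, `folds`,
#'   `repeats`.
#' @export
cross_validate <- function(dataset, spec) {
  stopifnot(inherits(dataset, "roi_dataset"), inherits(spec, "classifier_spec"))
  rows <- dataset_rows(dataset, "train")
  x <- dataset$features[rows, , drop = FALSE]
  y <- droplevels(dataset$labels[rows])
  y <- factor(as.character(y), levels = c("exclude", "include"))
  check_cv_feasible(y, spec)
  beta <- objective_beta(spec)
  scores <- numeric(0)
  for (r in seq_len(spec$cv_repeats)) {
    folds <- withr::with_seed(spec$seed + (r - 1L),
                              caret::createFolds(y, k = spec$cv_folds))
    for (fold in folds) {
      fit <- fit_classifier_core(x[-fold, , drop = FALSE], y[-fold], spec)
      pred <- predict_classifier_core(fit, x[fold, , drop = FALSE])
      cm <- confusion(y[fold], pred$label)
      scores <- c(scores, unname(prf_scores(cm, beta = beta)["f_beta"]))
    }
  }
  structure(
    list(scores = scores, mean = mean(scores), sd = stats::sd(scores),
         objective = spec$objective, beta = beta,
         folds = spec$cv_folds, repeats = spec$cv_repeats),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s = %.4f +/- %.4f (%d folds x %d repeats)\n",
              if (x$objective == "f1") "F1" else sprintf("F%.2g", x$beta),
              x$mean, x$sd, x$folds, x$repeats))
  invisible(x)
}

#' Train an include/exclude classifier
#'
#' Cross-validates the spec on the training rows (optional), then fits the
#' pipeline on all training rows. Any preprocessing fitted during training
#' (PCA) uses training rows only — test rows never leak into fitted state.
#'
#' @param dataset An `roi_dataset`.
#' @param spec A [classifier_spec()].
#' @param run_cv Compute a [cross_validate()] report before the final fit
#'   (default `TRUE`).
#' @return An object of class `classifier_bundle`: the classifier spec, the
#'   preprocessing recipe inherited from the dataset, the fitted model, the
#'   CV report, feature dimensions and a creation timestamp.
#' @export
train_classifier <- function(dataset, spec, run_cv = TRUE) {
  stopifnot(inherits(dataset, "roi_dataset"), inherits(spec, "classifier_spec"))
  rows <- dataset_rows(dataset, "train")
  x <- dataset$features[rows, , drop = FALSE]
  y <- factor(as.character(dataset$labels[rows]), levels = c("exclude", "include"))
  if (any(table(y) == 0L)) {
    stop("train_classifier: both classes must be present in the training rows")
  }
  cv <- if (run_cv) cross_validate(dataset, spec) else NULL
  fit <- withr::with_seed(spec$seed, fit_classifier_core(x, y, spec))
  structure(
    list(spec = spec, preprocess = dataset$spec, fit = fit,
         cv_report = cv, input_dim = fit$input_dim,
         feature_dim = fit$model_dim,
         format = "roicurate_bundle_v1",
         created = format(Sys.time(), tz = "UTC", usetz = TRUE)),
    class = "classifier_bundle"
  )
}

#' @export
print.classifier_bundle <- function(x, ...) {
  cat(sprintf("<classifier_bundle> %s%s, %d -> %d features, created %s\n",
              x$spec$family, if (x$spec$use_pca) " + PCA" else "",
              x$input_dim, x$feature_dim, x$created))
  if (!is.null(x$cv_report)) print(x$cv_report)
  invisible(x)
}

#' Predict include/exclude labels with confidences
#'
#' @param object A `classifier_bundle`.
#' @param newdata A feature matrix (n x input_dim), an `roi_dataset`, an
#'   `roi_collection`, a single [roi()], or a list of ROIs. Raw ROIs are
#'   preprocessed with the bundle's stored recipe.
#' @param ... Unused.
#' @return A data.frame with columns `roi_id`, `label`
#'   (`include`/`exclude`), and `confidence` (certainty assigned to the
#'   predicted label; `>= 0.5` for two-class probabilities).
#' @export
predict.classifier_bundle <- function(object, newdata, ...) {
  if (inherits(newdata, "roi")) newdata <- list(newdata)
  if (is.list(newdata) && !is.data.frame(newdata) &&
      !inherits(newdata, c("roi_collection", "roi_dataset")) &&
      all(vapply(newdata, inherits, logical(1), "roi"))) {
    if (length(newdata) == 0L) {
      return(data.frame(roi_id = character(0), label = character(0),
                        confidence = numeric(0)))
    }
    x <- do.call(rbind, lapply(newdata, build_feature_vector, spec = object$preprocess))
    rownames(x) <- vapply(newdata, `[[`, character(1), "id")
  } else if (inherits(newdata, "roi_collection")) {
    x <- build_feature_matrix(newdata, object$preprocess)
  } else if (inherits(newdata, "roi_dataset")) {
    x <- newdata$features
  } else if (is.matrix(newdata)) {
    x <- newdata
  } else {
    stop("predict: unsupported input of class ", paste(class(newdata), collapse = "/"))
  }
  out <- predict_classifier_core(object$fit, x)
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("row_%d", seq_len(nrow(x)))
  data.frame(roi_id = ids, label = out$label, confidence = out$confidence,
             row.names = NULL)
}

#' Confidence-based triage policy
#'
#' @param auto_threshold Confidence in `(0.5, 1]` below which a prediction is
#'   queued for human review rather than auto-routed.
#' @return An object of class `triage_policy`.
#' @export
triage_policy <- function(auto_threshold = 0.9) {
  if (!(auto_threshold > 0.5 && auto_threshold <= 1)) {
    stop("triage_policy: auto_threshold must be in (0.5, 1]")
  }
  structure(list(auto_threshold = auto_threshold), class = "triage_policy")
}

#' Triage predictions into auto-routed and review queues
#'
#' Partitions predictions: those with `confidence >= auto_threshold` are
#' routed automatically by their predicted label; the rest go to the human
#' review queue. Input order is preserved within each list.
#'
#' @param predictions A data.frame from [predict.classifier_bundle()].
#' @param policy A [triage_policy()].
#' @return List with data.frames `auto_include`, `auto_exclude`,
#'   `review_queue`.
#' @export
triage <- function(predictions, policy = triage_policy()) {
  stopifnot(inherits(policy, "triage_policy"),
            all(c("label", "confidence") %in% names(predictions)))
  queued <- predictions$confidence < policy$auto_threshold
  list(
    auto_include = predictions[!queued & predictions$label == "include", , drop = FALSE],
    auto_exclude = predictions[!queued & predictions$label == "exclude", , drop = FALSE],
    review_queue = predictions[queued, , drop = FALSE]
  )
}

#' Persist / restore a classifier bundle
#'
#' The bundle is written as a single RDS archive carrying a format tag;
#' loading verifies the tag and restores a bundle whose predictions are
#' identical to the original's.
#'
#' @param bundle A `classifier_bundle`.
#' @param path File path.
#' @return `path` invisibly for `save_bundle`; the bundle for `load_bundle`.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "classifier_bundle"))
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) stop("load_bundle: file not found: ", path)
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("load_bundle: '", path, "' is not a readable bundle archive (",
         conditionMessage(e), ")")
  })
  if (!inherits(obj, "classifier_bundle") ||
      !identical(obj$format, "roicurate_bundle_v1")) {
    stop("load_bundle: incompatible bundle format in '", path,
         "' (expected roicurate_bundle_v1)")
  }
  obj
}
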