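as_label01 <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop("labels must be 0/1, logical, or include/exclude")
    return(as.integer(x))
  }
  lx <- tolower(x)
  bad <- !lx %in% c("include", "exclude")
  if (any(bad)) stop("unknown label token(s): ", paste(unique(x[bad]), collapse = ", "))
  as.integer(lx == "include")
}

#' Confusion counts and row-proportion matrix
#'
#' Positive class is `include`. The proportion matrix is row-normalized per
#' true class (each row of a data-derived matrix sums to 1), the form used to
#' annotate curation confusion-matrix figures.
#'
#' @param truth,predicted Equal-length label vectors (include/exclude
#'   strings, factors, logicals, or 0/1 with 1 = include).
#' @return An object of class `confusion`: list with `counts` (named vector
#'   tp/fp/fn/tn), `proportions` (2 x 2 matrix, rows = true
#'   include/exclude, columns = predicted include/exclude), `n`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop(sprintf("confusion: length mismatch: truth %d vs predicted %d",
                 length(truth), length(predicted)))
  }
  t1 <- as_label01(truth); p1 <- as_label01(predicted)
  tp <- sum(t1 == 1L & p1 == 1L); fn <- sum(t1 == 1L & p1 == 0L)
  fp <- sum(t1 == 0L & p1 == 1L); tn <- sum(t1 == 0L & p1 == 0L)
  prop <- rbind(
    include = c(tp, fn) / max(tp + fn, 1L),
    exclude = c(fp, tn) / max(fp + tn, 1L)
  )
  colnames(prop) <- c("include", "exclude")
  structure(
    list(counts = c(tp = tp, fp = fp, fn = fn, tn = tn),
         proportions = prop, n = length(t1)),
    class = "confusion"
  )
}

#' @export
print.confusion <- function(x, digits = 3, ...) {
  cat(sprintf("<confusion> n = %d (tp %d, fp %d, fn %d, tn %d)\n", x$n,
              x$counts["tp"], x$counts["fp"], x$counts["fn"], x$counts["tn"]))
  print(round(x$proportions, digits))
  invisible(x)
}

#' Render a confusion matrix as a shaded grid
#'
#' @param x A `confusion` object.
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.confusion <- function(x, main = "Confusion matrix", ...) {
  p <- x$proportions
  graphics::image(1:2, 1:2, t(p[2:1, ]), col = grDevices::hcl.colors(32, "Blues", rev = TRUE),
                  axes = FALSE, xlab = "Predicted", ylab = "True", main = main,
                  zlim = c(0, 1), ...)
  graphics::axis(1, at = 1:2, labels = colnames(p))
  graphics::axis(2, at = 2:1, labels = rownames(p))
  for (i in 1:2) for (j in 1:2) {
    graphics::text(j, 3 - i, sprintf("%.3f", p[i, j]),
                   col = if (p[i, j] > 0.5) "white" else "black")
  }
  invisible(x)
}

#' Precision, recall and F-beta from confusion counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`,
#' `f_beta = (1 + beta^2) P R / (beta^2 P + R)`. A zero denominator yields 0
#' and sets the `"degenerate"` attribute. `beta > 1` weights recall (false
#' negatives) more heavily, `beta < 1` precision; `beta = 1` is the F1 score.
#'
#' @param x A `confusion` object or a named numeric vector with `tp`, `fp`,
#'   `fn`.
#' @param beta Positive recall weight. Default 1.
#' @return Named numeric vector `precision`, `recall`, `f_beta` (with
#'   attributes `beta` and `degenerate`).
#' @export
prf_scores <- function(x, beta = 1) {
  if (beta <= 0) stop("prf_scores: beta must be > 0")
  counts <- if (inherits(x, "confusion")) x$counts else x
  if (!all(c("tp", "fp", "fn") %in% names(counts))) {
    stop("prf_scores: need named counts tp, fp, fn")
  }
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  degenerate <- FALSE
  precision <- if (tp + fp > 0) tp / (tp + fp) else {degenerate <- TRUE; 0}
  recall <- if (tp + fn > 0) tp / (tp + fn) else {degenerate <- TRUE; 0}
  denom <- beta^2 * precision + recall
  f <- if (denom > 0) (1 + beta^2) * precision * recall / denom else {degenerate <- TRUE; 0}
  structure(c(precision = precision, recall = recall, f_beta = f),
            beta = beta, degenerate = degenerate)
}

#' Agreement between two raters' labels
#'
#' @param labels_a,labels_b Equal-length label vectors over the same ROIs.
#' @param ids_a,ids_b Optional id vectors; when given, `labels_b` is aligned
#'   to `ids_a` and any id mismatch is an error.
#' @return List with `agreement` (proportion of identical labels) and
#'   `table` (rater A x rater B count matrix).
#' @export
interrater_agreement <- function(labels_a, labels_b, ids_a = NULL, ids_b = NULL) {
  if (!is.null(ids_a) || !is.null(ids_b)) {
    if (is.null(ids_a) || is.null(ids_b)) {
      stop("interrater_agreement: supply both id vectors or neither")
    }
    if (!setequal(ids_a, ids_b) || anyDuplicated(ids_a) || anyDuplicated(ids_b)) {
      stop("interrater_agreement: alignment error: rater id sets differ")
    }
    labels_b <- labels_b[match(ids_a, ids_b)]
  }
  if (length(labels_a) != length(labels_b)) {
    stop("interrater_agreement: label vectors differ in length")
  }
  a <- factor(c("exclude", "include")[as_label01(labels_a) + 1L],
              levels = c("include", "exclude"))
  b <- factor(c("exclude", "include")[as_label01(labels_b) + 1L],
              levels = c("include", "exclude"))
  list(agreement = mean(a == b),
       table = table(rater_a = a, rater_b = b))
}

#' Cohen's d standardized mean difference
#'
#' `d = (mean(a) - mean(b)) / s_pooled` with
#' `s_pooled = sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`
#' and sample variances on `n - 1` denominators.
#'
#' @param a,b Numeric samples, each of size >= 2.
#' @return The effect size (positive when `a` has the larger mean).
#' @export
cohens_d <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("cohens_d: each sample needs >= 2 values")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) stop("cohens_d: undefined effect, pooled standard deviation is 0")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Confidence separation between correct and incorrect predictions
#'
#' Splits predictions by predicted class and compares the confidence
#' distributions of correct vs. incorrect calls with Cohen's d: for
#' predicted-include ROIs, true positives vs. false positives; for
#' predicted-exclude ROIs, true negatives vs. false negatives. A well
#' calibrated classifier is less confident on its mistakes, giving large
#' positive d — the basis for confidence-based triage.
#'
#' @param predictions Data.frame with `label` and `confidence` (as returned
#'   by [predict.classifier_bundle()]).
#' @param truth True labels aligned with `predictions` rows.
#' @return List with elements `include` and `exclude`, each a list holding
#'   the two confidence samples (`correct`, `incorrect`), their sizes, and
#'   `d` (`NA` with `defined = FALSE` when either group has < 2 members).
#' @export
certainty_analysis <- function(predictions, truth) {
  stopifnot(all(c("label", "confidence") %in% names(predictions)))
  if (nrow(predictions) != length(truth)) {
    stop("certainty_analysis: predictions and truth differ in length")
  }
  p1 <- as_label01(predictions$label)
  t1 <- as_label01(truth)
  conf <- as.numeric(predictions$confidence)
  one_side <- function(cls) {
    correct <- conf[p1 == cls & t1 == cls]
    incorrect <- conf[p1 == cls & t1 != cls]
    defined <- length(correct) >= 2 && length(incorrect) >= 2
    d <- NA_real_
    if (defined) {
      d <- tryCatch(cohens_d(correct, incorrect), error = function(e) NA_real_)
      defined <- is.finite(d)
    }
    list(correct = correct, incorrect = incorrect,
         n_correct = length(correct), n_incorrect = length(incorrect),
         d = d, defined = defined)
  }
  list(include = one_side(1L), exclude = one_side(0L))
}

#' F-score learning curve over increasing training-set sizes
#'
#' For each requested size, a stratified subsample of the training rows is
#' drawn (nested by default: each size's sample contains the previous one,
#' which reduces curve variance), the classifier is fitted on it, and the
#' objective score on the fixed test rows is recorded. Change points of the
#' score series are located with [detect_change_points()]; the largest change
#' point marks the size at which performance plateaus.
#'
#' @param dataset An `roi_dataset` with both train and test rows.
#' @param spec A [classifier_spec()] (fitted directly per size; no inner CV).
#' @param sizes Strictly increasing training-set sizes, `max <= n_train`.
#' @param seed Integer seed for the subsampling (default: the spec's seed).
#' @param nested Nested (`TRUE`, default) or independent subsamples.
#' @param change_penalty PELT penalty; default `2 * log(n) * var(scores)`.
#' @return An object of class `learning_curve`: list with `sizes`, `scores`,
#'   `change_points` (1-based indices into `sizes`), `change_point_sizes`,
#'   `plateau_size` (largest change-point size, `NA` if none), `penalty`.
#' @export
learning_curve <- function(dataset, spec, sizes, seed = NULL, nested = TRUE,
                           change_penalty = NULL) {
  stopifnot(inherits(dataset, "roi_dataset"), inherits(spec, "classifier_spec"))
  sizes <- as.integer(sizes)
  if (length(sizes) < 1L || any(diff(sizes) <= 0L)) {
    stop("learning_curve: sizes must be strictly increasing")
  }
  if (is.null(seed)) seed <- spec$seed
  tr <- dataset_rows(dataset, "train"); te <- dataset_rows(dataset, "test")
  if (length(te) == 0L) stop("learning_curve: dataset has no test rows")
  if (max(sizes) > length(tr)) {
    stop(sprintf("learning_curve: max size %d exceeds %d training rows",
                 max(sizes), length(tr)))
  }
  y <- factor(as.character(dataset$labels[tr]), levels = c("exclude", "include"))
  prop <- table(y) / length(y)
  if (any(round(min(sizes) * prop) < 2)) {
    stop(sprintf("learning_curve: size error: smallest size %d leaves a class with < 2 members",
                 min(sizes)))
  }
  beta <- objective_beta(spec)
  truth_test <- dataset$labels[te]
  x_test <- dataset$features[te, , drop = FALSE]
  scores <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    s <- sizes[i]
    counts <- round(s * prop)
    counts[which.max(counts)] <- counts[which.max(counts)] + (s - sum(counts))
    pick_seed <- if (nested) seed else seed + i
    idx <- withr::with_seed(pick_seed, {
      unlist(lapply(levels(y), function(cl) {
        pool <- sample(which(y == cl))  # class-wise permutation
        pool[seq_len(counts[[cl]])]    # nested: prefixes of one permutation
      }), use.names = FALSE)
    })
    fit <- fit_classifier_core(dataset$features[tr[idx], , drop = FALSE],
                               y[idx], spec)
    pred <- predict_classifier_core(fit, x_test)
    scores[i] <- unname(prf_scores(confusion(truth_test, pred$label),
                                   beta = beta)["f_beta"])
  }
  n <- length(scores)
  if (is.null(change_penalty)) {
    change_penalty <- 2 * log(n) * max(stats::var(scores), 1e-12)
  }
  cps <- if (n >= 2) detect_change_points(scores, change_penalty) else integer(0)
  structure(
    list(sizes = sizes, scores = scores, change_points = cps,
         change_point_sizes = sizes[cps],
         plateau_size = if (length(cps)) sizes[max(cps)] else NA_integer_,
         penalty = change_penalty),
    class = "learning_curve"
  )
}

#' @export
print.learning_curve <- function(x, ...) {
  cat("<learning_curve>\n")
  print(data.frame(size = x$sizes, score = round(x$scores, 4)))
  cat(sprintf("change points at sizes: %s (penalty %.4g)\n",
              if (length(x$change_point_sizes))
                paste(x$change_point_sizes, collapse = ", ") else "none",
              x$penalty))
  invisible(x)
}

#' @export
plot.learning_curve <- function(x, ...) {
  graphics::plot(x$sizes, x$scores, type = "b", log = "x",
                 xlab = "training ROIs", ylab = "test score", ...)
  if (length(x$change_point_sizes)) {
    graphics::abline(v = x$change_point_sizes, lty = 2, col = "red")
  }
  invisible(x)
}

#' Export a learning curve as a size,score table
#' @param curve A `learning_curve`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
save_learning_curve <- function(curve, path) {
  stopifnot(inherits(curve, "learning_curve"))
  utils::write.csv(data.frame(size = curve$sizes, score = curve$scores),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# within-segment sum of squared deviations from the segment mean,
# computed from cumulative sums; a/b are 1-based inclusive
segment_cost <- function(cs, cs2, a, b) {
  s <- cs[b + 1L] - cs[a]
  s2 <- cs2[b + 1L] - cs2[a]
  s2 - s^2 / (b - a + 1L)
}

#' Change-point detection by PELT
#'
#' Finds the segmentation of a numeric series minimizing the total
#' within-segment squared deviation from segment means (the Gaussian
#' mean-shift cost) plus a per-change-point penalty, using the Pruned Exact
#' Linear Time algorithm. The result is the exact optimum (identical to
#' exhaustive segmentation search); candidate pruning only removes provably
#' suboptimal split points.
#'
#' @param x Numeric series, length >= 2.
#' @param penalty Positive penalty per change point. Default
#'   `2 * log(n) * var(x)` (with a small floor on the variance).
#' @return Integer vector of change points as 1-based indices of the first
#'   element of each new segment (empty when the series is best fitted by a
#'   single segment).
#' @export
detect_change_points <- function(x, penalty = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("detect_change_points: series must have length >= 2")
  if (is.null(penalty)) penalty <- 2 * log(n) * max(stats::var(x), 1e-12)
  if (!is.numeric(penalty) || penalty <= 0) {
    stop("detect_change_points: penalty must be > 0")
  }
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  f <- c(-penalty, rep(Inf, n))   # f[t + 1] = optimal cost of x[1..t]
  prev <- integer(n + 1L)
  cand <- 0L
  for (t in seq_len(n)) {
    vals <- vapply(cand, function(s) f[s + 1L] + segment_cost(cs, cs2, s + 1L, t),
                   numeric(1)) + penalty
    best <- which.min(vals)
    f[t + 1L] <- vals[best]
    prev[t + 1L] <- cand[best]
    keep <- vals - penalty <= f[t + 1L]
    cand <- c(cand[keep], t)
  }
  cps <- integer(0)
  t <- n
  while (t > 0L) {
    s <- prev[t + 1L]
    if (s > 0L) cps <- c(s, cps)
    t <- s
  }
  cps + 1L
}
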