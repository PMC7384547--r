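#' Preprocessing recipe for ROI feature vectors
#'
#' Defines how an ROI is turned into a fixed-length feature vector: the
#' footprint is cropped to a `crop_size x crop_size` window centered on its
#' peak pixel, the trace is cropped (or zero-padded) to `trace_len` frames and
#' optionally min-max normalized, and the two blocks are concatenated. The
#' defaults (80 px crop, 500 frames) give 6,400 spatial + 500 trace = 6,900
#' features per ROI.
#'
#' @param crop_size Side length of the footprint crop in pixels. Default 80.
#' @param trace_len Number of trace frames kept. Default 500 (100 s at 5 Hz).
#' @param trace_norm `"minmax"` (per-trace rescale to `[0, 1]`; constant
#'   traces map to all zeros) or `"none"`.
#' @param pad_value Fill value for crop regions outside the FOV and for
#'   right-padding short traces. Default 0.
#' @param modality Which feature block(s) to emit: `"combined"` (default),
#'   `"spatial"`, or `"trace"`; supports spatial-only / trace-only
#'   classifier comparisons.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(crop_size = 80, trace_len = 500,
                            trace_norm = c("minmax", "none"), pad_value = 0,
                            modality = c("combined", "spatial", "trace")) {
  crop_size <- as.integer(crop_size); trace_len <- as.integer(trace_len)
  if (crop_size < 1L || trace_len < 1L) {
    stop("preprocess_spec: crop_size and trace_len must be >= 1")
  }
  structure(
    list(crop_size = crop_size, trace_len = trace_len,
         trace_norm = match.arg(trace_norm), pad_value = as.numeric(pad_value),
         modality = match.arg(modality)),
    class = "preprocess_spec"
  )
}

#' Feature dimension implied by a preprocessing recipe
#' @param spec A [preprocess_spec()].
#' @return Integer length of the feature vector.
#' @export
feature_dim <- function(spec) {
  stopifnot(inherits(spec, "preprocess_spec"))
  switch(spec$modality,
         combined = spec$crop_size^2 + spec$trace_len,
         spatial  = spec$crop_size^2,
         trace    = spec$trace_len)
}

# argmax pixel; ties broken by smallest row, then smallest column
peak_index <- function(m) {
  w <- which(m == max(m), arr.ind = TRUE)
  w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
  as.integer(w[1, ])
}

#' Crop a footprint around its peak pixel
#'
#' Returns a `crop_size x crop_size` window centered on the brightest pixel of
#' the footprint. In 0-based coordinates the peak lands at
#' `(floor(crop_size/2), floor(crop_size/2))`; window regions outside the FOV
#' are filled with `pad_value`. Ties for the peak are broken by smallest row,
#' then smallest column.
#'
#' @param footprint Numeric matrix with at least one strictly positive pixel.
#' @param crop_size Window side length in pixels.
#' @param pad_value Fill value outside the FOV. Default 0.
#' @return A `crop_size x crop_size` numeric matrix.
#' @export
crop_footprint <- function(footprint, crop_size, pad_value = 0) {
  stopifnot(is.matrix(footprint), is.numeric(footprint))
  crop_size <- as.integer(crop_size)
  if (crop_size < 1L) stop("crop_footprint: crop_size must be >= 1")
  if (!any(footprint > 0)) {
    stop("crop_footprint: degenerate input, footprint has no strictly positive pixel")
  }
  pk <- peak_index(footprint)
  half <- crop_size %/% 2L
  rows <- (pk[1] - half):(pk[1] - half + crop_size - 1L)
  cols <- (pk[2] - half):(pk[2] - half + crop_size - 1L)
  out <- matrix(pad_value, crop_size, crop_size)
  rok <- rows >= 1L & rows <= nrow(footprint)
  cok <- cols >= 1L & cols <= ncol(footprint)
  out[rok, cok] <- footprint[rows[rok], cols[cok], drop = FALSE]
  out
}

#' Crop, pad and normalize a calcium trace
#'
#' Keeps the first `trace_len` frames (right-padding shorter traces with
#' `pad_value` first), then applies per-trace min-max normalization when
#' `trace_norm = "minmax"`: non-constant traces are mapped onto `[0, 1]`,
#' constant traces onto all zeros. The operation is idempotent for traces
#' already of length `trace_len`.
#'
#' @param trace Numeric vector.
#' @param trace_len Output length in frames.
#' @param trace_norm `"minmax"` or `"none"`.
#' @param pad_value Padding value for short traces. Default 0.
#' @return Numeric vector of length `trace_len`.
#' @export
standardize_trace <- function(trace, trace_len, trace_norm = "minmax",
                              pad_value = 0) {
  trace_len <- as.integer(trace_len)
  if (trace_len < 1L) stop("standardize_trace: trace_len must be >= 1")
  if (length(trace) < 1L) stop("standardize_trace: empty trace")
  x <- as.numeric(trace)[seq_len(min(length(trace), trace_len))]
  if (length(x) < trace_len) x <- c(x, rep(pad_value, trace_len - length(x)))
  if (identical(trace_norm, "minmax")) {
    rng <- range(x)
    if (rng[2] > rng[1]) x <- (x - rng[1]) / (rng[2] - rng[1]) else x[] <- 0
  }
  x
}

#' Build the feature vector of one ROI
#'
#' Row-major flattened peak-centered footprint crop, followed by the
#' standardized trace (blocks selected by the recipe's `modality`).
#'
#' @param roi An [roi()] object.
#' @param spec A [preprocess_spec()].
#' @return Numeric vector of length [feature_dim()].
#' @export
build_feature_vector <- function(roi, spec = preprocess_spec()) {
  stopifnot(inherits(roi, "roi"), inherits(spec, "preprocess_spec"))
  spatial <- NULL; tr <- NULL
  if (spec$modality %in% c("combined", "spatial")) {
    crop <- crop_footprint(roi$footprint, spec$crop_size, spec$pad_value)
    spatial <- as.vector(t(crop))  # row-major flatten
  }
  if (spec$modality %in% c("combined", "trace")) {
    tr <- standardize_trace(roi$trace, spec$trace_len, spec$trace_norm,
                            spec$pad_value)
  }
  c(spatial, tr)
}

#' Build the feature matrix of a whole collection
#'
#' @param collection An `roi_collection`; all-zero footprints are skipped only
#'   in `modality = "trace"` mode, otherwise they raise the degenerate-input
#'   error from [crop_footprint()].
#' @param spec A [preprocess_spec()].
#' @return Numeric matrix (`n_roi x feature_dim`) with ROI ids as row names.
#' @export
build_feature_matrix <- function(collection, spec = preprocess_spec()) {
  stopifnot(inherits(collection, "roi_collection"))
  K <- n_roi(collection)
  d <- feature_dim(spec)
  out <- matrix(NA_real_, K, d, dimnames = list(collection$ids, NULL))
  for (k in seq_len(K)) {
    out[k, ] <- build_feature_vector(get_roi(collection, k), spec)
  }
  out
}

#' Assemble a labeled train/test dataset from a collection
#'
#' Computes feature vectors for every ROI and draws a stratified train/test
#' split: each class contributes `round(test_fraction * n_class)` ROIs to the
#' test set, so test-set class proportions match the full dataset's within one
#' sample per class. The split is a deterministic function of `seed`.
#'
#' @param collection An `roi_collection` in which every ROI is labeled
#'   `include` or `exclude`.
#' @param spec A [preprocess_spec()]; its `modality` selects spatial-only,
#'   trace-only or combined features.
#' @param test_fraction Proportion of ROIs held out for testing (0 < f < 1).
#'   Default 0.2.
#' @param seed Integer seed controlling the split.
#' @return An object of class `roi_dataset`: list with `features` (n x d
#'   matrix), `labels` (factor, levels exclude/include), `ids`, `split`
#'   (`"train"`/`"test"`), `provenance` (source tags), and the `spec`.
#' @export
assemble_dataset <- function(collection, spec = preprocess_spec(),
                             test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(collection, "roi_collection"))
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("assemble_dataset: test_fraction must be in (0, 1)")
  }
  unl <- collection$labels == "unlabeled"
  if (any(unl)) {
    stop("assemble_dataset: unlabeled ROIs present: ",
         paste(utils::head(collection$ids[unl], 10), collapse = ", "),
         if (sum(unl) > 10) sprintf(" ... (%d total)", sum(unl)) else "")
  }
  y <- factor(collection$labels, levels = c("exclude", "include"))
  if (any(table(y) < 2L)) {
    stop("assemble_dataset: stratification requires >= 2 ROIs per class; got ",
         paste(sprintf("%s=%d", levels(y), table(y)), collapse = ", "))
  }
  x <- build_feature_matrix(collection, spec)
  split <- rep("train", n_roi(collection))
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      n_test <- round(test_fraction * length(idx))
      if (n_test > 0) split[sample(idx, n_test)] <- "test"
    }
  })
  structure(
    list(features = x, labels = y, ids = collection$ids, split = split,
         provenance = collection$source, spec = spec),
    class = "roi_dataset"
  )
}

#' @export
print.roi_dataset <- function(x, ...) {
  cat(sprintf("<roi_dataset> %d ROIs x %d features (%s), %d train / %d test, %d include / %d exclude\n",
              nrow(x$features), ncol(x$features), x$spec$modality,
              sum(x$split == "train"), sum(x$split == "test"),
              sum(x$labels == "include"), sum(x$labels == "exclude")))
  invisible(x)
}

# rows of a dataset by split tag
dataset_rows <- function(dataset, part = c("train", "test")) {
  part <- match.arg(part)
  stopifnot(inherits(dataset, "roi_dataset"))
  which(dataset$split == part)
}
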