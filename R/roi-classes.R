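#' Field-of-view geometry
#'
#' Describes the imaging geometry shared by all ROIs of a recording: the
#' field-of-view (FOV) size in pixels, the number of frames, and the frame
#' rate. The default frame rate of 5 Hz matches typical miniscope acquisition,
#' where 500 frames correspond to 100 s of recording.
#'
#' @param height,width FOV size in pixels (`>= 1`).
#' @param n_frames Number of frames in each calcium trace (`>= 1`).
#' @param frame_rate Acquisition rate in Hz. Default 5.
#' @return An object of class `fov_geometry`.
#' @export
fov_geometry <- function(height, width, n_frames, frame_rate = 5) {
  height <- as.integer(height); width <- as.integer(width)
  n_frames <- as.integer(n_frames)
  if (height < 1L || width < 1L || n_frames < 1L) {
    stop("fov_geometry: height, width and n_frames must all be >= 1")
  }
  structure(
    list(height = height, width = width, n_frames = n_frames,
         frame_rate = as.numeric(frame_rate)),
    class = "fov_geometry"
  )
}

#' @export
print.fov_geometry <- function(x, ...) {
  cat(sprintf("<fov_geometry> %d x %d px, %d frames @ %g Hz\n",
              x$height, x$width, x$n_frames, x$frame_rate))
  invisible(x)
}

VALID_LABELS <- c("include", "exclude", "unlabeled")

canonical_label <- function(label) {
  lab <- tolower(as.character(label))
  bad <- !lab %in% VALID_LABELS
  if (any(bad)) {
    stop("unknown label token(s): ", paste(unique(label[bad]), collapse = ", "),
         " (expected include/exclude/unlabeled)")
  }
  lab
}

#' A single extracted ROI
#'
#' One putative neuron as produced by source extraction: a non-negative 2-D
#' spatial footprint (pixel weights over the FOV) and a 1-D calcium trace,
#' plus an optional curation label.
#'
#' @param id Character identifier, unique within a collection.
#' @param footprint Numeric matrix (height x width) of non-negative pixel
#'   weights. An all-zero footprint is permitted but flagged downstream.
#' @param trace Numeric vector of fluorescence over frames.
#' @param label One of `"include"`, `"exclude"`, `"unlabeled"`.
#' @param source Free-text provenance tag.
#' @return An object of class `roi`.
#' @export
roi <- function(id, footprint, trace, label = "unlabeled", source = "") {
  if (!is.matrix(footprint) || !is.numeric(footprint)) {
    stop("roi: footprint must be a numeric matrix")
  }
  if (any(footprint < 0)) stop("roi: footprint must be non-negative")
  structure(
    list(id = as.character(id), footprint = footprint,
         trace = as.numeric(trace), label = canonical_label(label),
         source = as.character(source)),
    class = "roi"
  )
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %s: %d x %d footprint (peak %.3g), %d-frame trace, label=%s\n",
              x$id, nrow(x$footprint), ncol(x$footprint), max(x$footprint),
              length(x$trace), x$label))
  invisible(x)
}

#' A collection of ROIs sharing one field of view
#'
#' Column-bound storage of many ROIs: footprints as a `height x width x K`
#' array, traces as a `K x n_frames` matrix, with per-ROI ids, labels and
#' provenance. ROIs whose footprint has no strictly positive pixel are
#' retained and recorded in the `zero_footprint` flag vector rather than
#' dropped, so that removal decisions stay with downstream filters.
#'
#' @param geometry An [fov_geometry()].
#' @param footprints `height x width x K` numeric array (a `height x width`
#'   matrix is accepted for K = 1).
#' @param traces `K x n_frames` numeric matrix.
#' @param ids Character vector of K unique ids (default `roi_00001`, ...).
#' @param labels Character vector of K labels (default `"unlabeled"`).
#' @param source Character vector of K provenance tags (recycled).
#' @return An object of class `roi_collection`.
#' @export
roi_collection <- function(geometry, footprints, traces, ids = NULL,
                           labels = NULL, source = "") {
  stopifnot(inherits(geometry, "fov_geometry"))
  if (is.matrix(footprints)) footprints <- array(footprints, c(dim(footprints), 1L))
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1L)
  d <- dim(footprints)
  if (length(d) != 3L) stop("roi_collection: footprints must be a height x width x K array")
  if (d[1] != geometry$height || d[2] != geometry$width) {
    stop(sprintf("roi_collection: footprint dims %d x %d do not match geometry %d x %d",
                 d[1], d[2], geometry$height, geometry$width))
  }
  K <- d[3]
  if (nrow(traces) != K) {
    stop(sprintf("roi_collection: %d traces for %d footprints", nrow(traces), K))
  }
  if (ncol(traces) != geometry$n_frames) {
    stop(sprintf("roi_collection: trace length %d does not match geometry n_frames %d",
                 ncol(traces), geometry$n_frames))
  }
  if (is.null(ids)) ids <- sprintf("roi_%05d", seq_len(K))
  ids <- as.character(ids)
  if (length(ids) != K) stop("roi_collection: need one id per ROI")
  if (anyDuplicated(ids)) {
    stop("roi_collection: duplicate ROI ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (is.null(labels)) labels <- rep("unlabeled", K)
  labels <- canonical_label(labels)
  if (length(labels) != K) stop("roi_collection: need one label per ROI")
  source <- rep_len(as.character(source), K)
  zero <- vapply(seq_len(K), function(k) !any(footprints[, , k] > 0), logical(1))
  structure(
    list(geometry = geometry, footprints = footprints, traces = traces,
         ids = ids, labels = labels, source = source, zero_footprint = zero),
    class = "roi_collection"
  )
}

#' Number of ROIs in a collection
#' @param collection An `roi_collection`.
#' @return Integer count.
#' @export
n_roi <- function(collection) {
  stopifnot(inherits(collection, "roi_collection"))
  dim(collection$footprints)[3]
}

#' Extract one ROI from a collection
#' @param collection An `roi_collection`.
#' @param i Integer position or character id.
#' @return An [roi()] object.
#' @export
get_roi <- function(collection, i) {
  stopifnot(inherits(collection, "roi_collection"))
  if (is.character(i)) {
    k <- match(i, collection$ids)
    if (is.na(k)) stop("get_roi: no ROI with id '", i, "'")
  } else {
    k <- as.integer(i)
    if (k < 1L || k > n_roi(collection)) stop("get_roi: index out of range")
  }
  roi(collection$ids[k], collection$footprints[, , k],
      collection$traces[k, ], collection$labels[k], collection$source[k])
}

#' Assemble a collection from a list of ROIs
#' @param rois List of [roi()] objects with identical geometry.
#' @param geometry An [fov_geometry()]; inferred from the first ROI when `NULL`
#'   (frame rate defaults to 5 Hz in that case).
#' @return An `roi_collection`.
#' @export
collect_rois <- function(rois, geometry = NULL) {
  stopifnot(length(rois) >= 1, all(vapply(rois, inherits, logical(1), "roi")))
  if (is.null(geometry)) {
    f <- rois[[1]]
    geometry <- fov_geometry(nrow(f$footprint), ncol(f$footprint), length(f$trace))
  }
  K <- length(rois)
  fp <- array(0, c(geometry$height, geometry$width, K))
  tr <- matrix(0, K, geometry$n_frames)
  for (k in seq_len(K)) {
    r <- rois[[k]]
    if (!identical(dim(r$footprint), c(geometry$height, geometry$width)) &&
        !identical(as.integer(dim(r$footprint)),
                   c(geometry$height, geometry$width))) {
      stop("collect_rois: ROI '", r$id, "' footprint does not match geometry")
    }
    if (length(r$trace) != geometry$n_frames) {
      stop("collect_rois: ROI '", r$id, "' trace length ", length(r$trace),
           " != n_frames ", geometry$n_frames)
    }
    fp[, , k] <- r$footprint
    tr[k, ] <- r$trace
  }
  roi_collection(geometry, fp, tr,
                 ids = vapply(rois, `[[`, character(1), "id"),
                 labels = vapply(rois, `[[`, character(1), "label"),
                 source = vapply(rois, `[[`, character(1), "source"))
}

#' Attach curation labels to a collection
#'
#' @param collection An `roi_collection`.
#' @param labels Named character vector (names = ROI ids) or the mapping
#'   returned by [load_labels()].
#' @param strict Error when `labels` contains ids absent from the collection
#'   (default `TRUE`).
#' @return The collection with labels applied; ids not named keep their
#'   current label.
#' @export
apply_labels <- function(collection, labels, strict = TRUE) {
  stopifnot(inherits(collection, "roi_collection"))
  if (is.null(names(labels)) || any(names(labels) == "")) {
    stop("apply_labels: labels must be a named vector of ROI ids")
  }
  unknown <- setdiff(names(labels), collection$ids)
  if (strict && length(unknown)) {
    stop("apply_labels: ids not in collection: ", paste(unknown, collapse = ", "))
  }
  hit <- intersect(names(labels), collection$ids)
  collection$labels[match(hit, collection$ids)] <- canonical_label(labels[hit])
  collection
}

#' @export
print.roi_collection <- function(x, ...) {
  tab <- table(factor(x$labels, levels = VALID_LABELS))
  cat(sprintf("<roi_collection> %d ROIs, %d x %d px, %d frames @ %g Hz\n",
              n_roi(x), x$geometry$height, x$geometry$width,
              x$geometry$n_frames, x$geometry$frame_rate))
  cat(sprintf("  labels: %d include / %d exclude / %d unlabeled",
              tab["include"], tab["exclude"], tab["unlabeled"]))
  if (any(x$zero_footprint)) {
    cat(sprintf("  (%d all-zero footprints flagged)", sum(x$zero_footprint)))
  }
  cat("\n")
  invisible(x)
}
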