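#' Read CNMF-E source-extraction output from an HDF5 / MAT v7.3 container
#'
#' Loads a spatial footprint matrix and a calcium trace matrix from an HDF5
#' container (MATLAB v7.3 files are HDF5 and read the same way) and assembles
#' an [roi_collection()]. The footprint dataset may be stored as
#' `pixels x K`, `K x pixels`, or `height x width x K` (in either axis
#' order); the trace dataset as `K x T` or `T x K`. The shared ROI count K is
#' resolved automatically by matching dimensions across the two datasets;
#' square matrices that leave K ambiguous require the explicit layout flags.
#'
#' Field-of-view images use the row-major convention: a flattened footprint
#' stores pixel `(y, x)` (0-based) at position `y * width + x`.
#'
#' @param path Path to the container.
#' @param dialect `"generic_hdf5"` (default), `"matlab_cnmfe"` (MAT v7.3;
#'   pre-7.3 MAT files are rejected with advice to re-save as v7.3), or
#'   `"caiman_hdf5"` (identical reader, keys default to
#'   `estimates/A` / `estimates/C`).
#' @param footprint_key,trace_key Dataset names (may include groups, e.g.
#'   `"neuron/A"`). Defaults `"A"` and `"C"` (per dialect).
#' @param fov Optional [fov_geometry()] giving height/width when the
#'   footprints are stored flattened and the file carries no geometry
#'   attributes. A square FOV is inferred when the pixel count is a perfect
#'   square.
#' @param footprint_layout `"auto"`, `"pixels_by_roi"`, or `"roi_by_pixels"`
#'   (for 3-D data: `"hwk"` or `"khw"`).
#' @param trace_layout `"auto"`, `"roi_by_time"`, or `"time_by_roi"`.
#' @param frame_rate Frame rate recorded in the geometry when the file has no
#'   `frame_rate` attribute. Default 5.
#' @return An [roi_collection()]. All-zero footprints are loaded, flagged in
#'   `zero_footprint`, and reported with a warning — never dropped.
#' @export
load_cnmfe_output <- function(path,
                              dialect = c("generic_hdf5", "matlab_cnmfe", "caiman_hdf5"),
                              footprint_key = NULL, trace_key = NULL,
                              fov = NULL,
                              footprint_layout = "auto",
                              trace_layout = "auto",
                              frame_rate = 5) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("load_cnmfe_output: file not found: ", path)
  if (is.null(footprint_key)) {
    footprint_key <- if (dialect == "caiman_hdf5") "estimates/A" else "A"
  }
  if (is.null(trace_key)) {
    trace_key <- if (dialect == "caiman_hdf5") "estimates/C" else "C"
  }
  if (!isTRUE(rhdf5::H5Fis_hdf5(path))) {
    stop("load_cnmfe_output: '", path, "' is not an HDF5 container",
         if (dialect == "matlab_cnmfe")
           " (pre-7.3 MAT file? re-save with MATLAB's '-v7.3' flag)" else "")
  }
  contents <- rhdf5::h5ls(path)
  available <- file.path(contents$group, contents$name)
  available <- sub("^/+", "", gsub("//", "/", available))
  for (key in c(footprint_key, trace_key)) {
    if (!sub("^/+", "", key) %in% available) {
      stop("load_cnmfe_output: dataset '", key, "' not found in ", path,
           "; available: ", paste(available, collapse = ", "))
    }
  }
  A <- h5_read_numeric(path, footprint_key)
  C <- h5_read_numeric(path, trace_key)
  attrs <- rhdf5::h5readAttributes(path, "/")
  if (length(dim(C)) != 2L) {
    stop("load_cnmfe_output: trace dataset '", trace_key, "' must be 2-D")
  }

  res <- resolve_orientation(A, C, footprint_layout, trace_layout)
  A <- res$A; C <- res$C; K <- res$K  # A: pixels x K or h x w x K; C: K x T

  # geometry
  h <- attrs$height; w <- attrs$width
  if (length(dim(A)) == 3L) {
    h <- dim(A)[1]; w <- dim(A)[2]
  } else if (is.null(h) || is.null(w)) {
    if (!is.null(fov)) {
      h <- fov$height; w <- fov$width
    } else {
      npix <- nrow(A)
      side <- round(sqrt(npix))
      if (side * side == npix) {
        h <- side; w <- side
      } else {
        stop("load_cnmfe_output: cannot infer field-of-view size for ", npix,
             " pixels; pass `fov = fov_geometry(height, width, n_frames)`")
      }
    }
  }
  h <- as.integer(h); w <- as.integer(w)
  if (length(dim(A)) == 2L) {
    if (h * w != nrow(A)) {
      stop(sprintf("load_cnmfe_output: %d x %d field of view does not match %d stored pixels",
                   h, w, nrow(A)))
    }
    # row-major pixel order: pixel (y, x) at position y * w + x (0-based)
    A <- array(apply(A, 2, function(v) t(matrix(v, w, h))), c(h, w, K))
  }
  fr <- if (!is.null(attrs$frame_rate)) as.numeric(attrs$frame_rate) else frame_rate
  geom <- fov_geometry(h, w, ncol(C), fr)

  ids <- if ("ids" %in% available) as.character(rhdf5::h5read(path, "ids"))
         else sprintf("roi_%05d", seq_len(K))
  labels <- if ("labels" %in% available) as.character(rhdf5::h5read(path, "labels"))
            else rep("unlabeled", K)
  src <- if ("source" %in% available) as.character(rhdf5::h5read(path, "source"))
         else rep(path, K)
  out <- roi_collection(geom, A, C, ids = ids, labels = labels, source = src)
  if (any(out$zero_footprint)) {
    warning("load_cnmfe_output: ", sum(out$zero_footprint),
            " ROI(s) with all-zero footprints flagged (not dropped): ",
            paste(utils::head(out$ids[out$zero_footprint], 5), collapse = ", "))
  }
  out
}

h5_read_numeric <- function(path, key) {
  x <- rhdf5::h5read(path, key)
  storage.mode(x) <- "double"
  x
}

# Resolve the shared ROI count K across footprint and trace arrays and
# reorient them to (pixels x K | h x w x K) and (K x T). The K axis of each
# array is either fixed by an explicit layout flag or matched against the
# other array's candidate dimensions; square arrays that leave the K axis
# ambiguous demand the explicit flag.
resolve_orientation <- function(A, C, footprint_layout, trace_layout) {
  dA <- dim(A); dC <- dim(C)
  # candidate K axes: for 3-D footprints the last or first axis, for 2-D
  # either axis; for traces either axis
  a_axes <- if (footprint_layout == "auto") {
    if (length(dA) == 3L) c(3L, 1L) else c(2L, 1L)
  } else {
    switch(footprint_layout,
           pixels_by_roi = 2L, roi_by_pixels = 1L, hwk = 3L, khw = 1L,
           stop("load_cnmfe_output: unknown footprint_layout '",
                footprint_layout, "'"))
  }
  c_axes <- if (trace_layout == "auto") c(1L, 2L) else {
    switch(trace_layout, roi_by_time = 1L, time_by_roi = 2L,
           stop("load_cnmfe_output: unknown trace_layout '", trace_layout, "'"))
  }
  if (any(a_axes > length(dA))) {
    stop("load_cnmfe_output: footprint_layout '", footprint_layout,
         "' does not fit a ", length(dA), "-D footprint dataset")
  }
  pairs <- expand.grid(a = a_axes, c = c_axes)
  pairs <- pairs[dA[pairs$a] == dC[pairs$c], , drop = FALSE]
  if (nrow(pairs) == 0L) {
    stop(sprintf("load_cnmfe_output: ROI count mismatch between footprints (dims %s) and traces (dims %s)",
                 paste(dA, collapse = "x"), paste(dC, collapse = "x")))
  }
  ks <- unique(dA[pairs$a])
  if (length(ks) > 1L) {
    stop("load_cnmfe_output: ambiguous orientation (K could be ",
         paste(ks, collapse = " or "),
         "); pass explicit footprint_layout/trace_layout")
  }
  K <- ks
  a_axis <- unique(pairs$a); c_axis <- unique(pairs$c)
  if (length(a_axis) > 1L) {
    stop("load_cnmfe_output: square footprint dataset leaves the orientation ambiguous; pass footprint_layout")
  }
  if (length(c_axis) > 1L) {
    stop("load_cnmfe_output: square trace matrix leaves the orientation ambiguous; pass trace_layout")
  }
  if (length(dA) == 3L) {
    if (a_axis == 1L) A <- aperm(A, c(2, 3, 1))  # K first -> K last
  } else if (a_axis == 1L) {
    A <- t(A)
  }
  if (c_axis == 2L) C <- t(C)
  list(A = A, C = C, K = K)
}

#' Read a CSV file of ROI labels
#'
#' Expects a header `id,label` with labels `include`/`exclude`
#' (case-insensitive).
#'
#' @param path CSV file path.
#' @return Named character vector mapping ROI id to `"include"`/`"exclude"`.
#' @export
load_labels <- function(path) {
  if (!file.exists(path)) stop("load_labels: file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!all(c("id", "label") %in% names(df))) {
    stop("load_labels: expected header columns id,label in ", path)
  }
  lab <- tolower(df$label)
  bad <- !lab %in% c("include", "exclude")
  if (any(bad)) {
    stop("load_labels: unknown label token(s) in row(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(df$label[bad]), collapse = ", "))
  }
  if (anyDuplicated(df$id)) {
    stop("load_labels: duplicate id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  stats::setNames(lab, df$id)
}

#' Write a collection to an HDF5 container
#'
#' Writes footprints as a `pixels x K` dataset `A` (row-major pixel order),
#' traces as a `K x T` dataset `C`, the id/label/source tables, and geometry
#' attributes (`height`, `width`, `n_frames`, `frame_rate`) on the root
#' group. [load_cnmfe_output()] on the result reproduces the collection
#' bit-exactly.
#'
#' @param collection An `roi_collection`.
#' @param path Output path (overwritten when present).
#' @return `path`, invisibly.
#' @export
save_collection <- function(collection, path) {
  stopifnot(inherits(collection, "roi_collection"))
  if (!dir.exists(dirname(path))) {
    stop("save_collection: cannot write '", path, "': directory does not exist")
  }
  if (file.exists(path)) unlink(path)
  ok <- tryCatch({
    rhdf5::h5createFile(path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) {
    stop("save_collection: cannot create HDF5 file at '", path, "'")
  }
  g <- collection$geometry
  K <- n_roi(collection)
  # row-major flatten of each footprint
  A <- vapply(seq_len(K),
              function(k) as.vector(t(collection$footprints[, , k])),
              numeric(g$height * g$width))
  A <- matrix(A, nrow = g$height * g$width, ncol = K)
  rhdf5::h5write(A, path, "A")
  rhdf5::h5write(collection$traces, path, "C")
  rhdf5::h5write(collection$ids, path, "ids")
  rhdf5::h5write(collection$labels, path, "labels")
  rhdf5::h5write(collection$source, path, "source")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(g$height, fid, "height")
  rhdf5::h5writeAttribute(g$width, fid, "width")
  rhdf5::h5writeAttribute(g$n_frames, fid, "n_frames")
  rhdf5::h5writeAttribute(g$frame_rate, fid, "frame_rate")
  invisible(path)
}

#' Export a feature dataset to HDF5
#'
#' Writes datasets `X` (n x d feature matrix), `y` (labels as
#' include/exclude strings), `ids`, and `split`, for interoperability with
#' external (e.g. AutoML) engines. [read_features()] round-trips the file.
#'
#' @param dataset An `roi_dataset` from [assemble_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_features <- function(dataset, path) {
  stopifnot(inherits(dataset, "roi_dataset"))
  if (!dir.exists(dirname(path))) {
    stop("export_features: cannot write '", path, "': directory does not exist")
  }
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(unname(dataset$features), path, "X")
  rhdf5::h5write(as.character(dataset$labels), path, "y")
  rhdf5::h5write(dataset$ids, path, "ids")
  rhdf5::h5write(dataset$split, path, "split")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(dataset$spec$crop_size, fid, "crop_size")
  rhdf5::h5writeAttribute(dataset$spec$trace_len, fid, "trace_len")
  rhdf5::h5writeAttribute(dataset$spec$trace_norm, fid, "trace_norm")
  rhdf5::h5writeAttribute(dataset$spec$modality, fid, "modality")
  invisible(path)
}

#' Read a feature dataset written by [export_features()]
#' @param path HDF5 file path.
#' @return An `roi_dataset`.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("read_features: file not found: ", path)
  x <- h5_read_numeric(path, "X")
  y <- factor(as.character(rhdf5::h5read(path, "y")),
              levels = c("exclude", "include"))
  ids <- as.character(rhdf5::h5read(path, "ids"))
  split <- as.character(rhdf5::h5read(path, "split"))
  a <- rhdf5::h5readAttributes(path, "/")
  spec <- preprocess_spec(
    crop_size = if (!is.null(a$crop_size)) a$crop_size else 80,
    trace_len = if (!is.null(a$trace_len)) a$trace_len else 500,
    trace_norm = if (!is.null(a$trace_norm)) a$trace_norm else "minmax",
    modality = if (!is.null(a$modality)) a$modality else "combined"
  )
  rownames(x) <- ids
  structure(
    list(features = x, labels = y, ids = ids, split = split,
         provenance = rep(path, length(ids)), spec = spec),
    class = "roi_dataset"
  )
}

#' Write ROI labels to CSV
#' @param labels Named character vector (id -> label) or an `roi_collection`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_labels <- function(labels, path) {
  if (inherits(labels, "roi_collection")) {
    labels <- stats::setNames(labels$labels, labels$ids)
  }
  utils::write.csv(data.frame(id = names(labels), label = unname(labels)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
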