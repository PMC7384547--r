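#' Specification of a simulated ground-truth dataset
#'
#' Parameters of the synthetic ROI generator. Positive ROIs emulate the
#' visual inclusion criteria for curated cells: a compact, bright anisotropic
#' Gaussian footprint of roughly neuronal size, and a calcium trace with fast
#' rise, slow decay and a stable baseline. Negative ("exclude") ROIs are
#' produced by corrupting a `neg_fraction` of positives with one of four
#' modes: `spatial` (footprint rescaled by a factor drawn from
#' `spatial_factors`), `trace` (Gaussian noise added at `trace_noise_sd`
#' times the trace's standard deviation), `both`, or `merged` (pixelwise /
#' framewise combination with a second, sacrificial ROI).
#'
#' @param n_rois Number of ROIs to generate.
#' @param fov An [fov_geometry()]. Default 80 x 80 px, 500 frames at 5 Hz.
#' @param neg_fraction Proportion of ROIs corrupted into negatives
#'   (`0 <= f < 1`). Default 0.15, the include/exclude imbalance typical of
#'   curated 1p datasets.
#' @param mode_weights Named non-negative weights over
#'   `c("spatial", "trace", "both", "merged")`. Default uniform.
#' @param spatial_factors Scale factors for the `spatial` mode; all positive,
#'   none equal to 1. Default `c(1/3, 1/2, 2, 3)`.
#' @param trace_noise_sd Noise magnitude for the `trace` mode, as a multiple
#'   of the clean trace's standard deviation. Default 2.
#' @param transient_rate Calcium transient rate in events/frame. Default 0.01
#'   (one event every 20 s at 5 Hz).
#' @param rise_frames,decay_frames Time constants (frames) of the
#'   double-exponential transient kernel. Defaults 2 and 10 (0.4 s rise, 2 s
#'   decay at 5 Hz, GCaMP6f-like).
#' @param footprint_radius Gaussian footprint radius in pixels. Default 4.
#' @param baseline_range,amp_range Uniform ranges for baseline fluorescence
#'   and transient amplitude (arbitrary units).
#' @param obs_noise_sd Observation noise added to traces. Default 0.02.
#' @param merge_rule `"sum"` (default; source extraction's generative model is
#'   additive) or `"mean"` for the merged mode.
#' @param resize_filter `"bilinear"` (default) or `"nearest"` for spatial
#'   rescaling.
#' @param seed Integer seed; the generated dataset is a pure function of the
#'   spec including this seed.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_rois = 2000,
                     fov = fov_geometry(80, 80, 500, 5),
                     neg_fraction = 0.15,
                     mode_weights = c(spatial = 1, trace = 1, both = 1, merged = 1),
                     spatial_factors = c(1/3, 1/2, 2, 3),
                     trace_noise_sd = 2,
                     transient_rate = 0.01,
                     rise_frames = 2,
                     decay_frames = 10,
                     footprint_radius = 4,
                     baseline_range = c(0.2, 1),
                     amp_range = c(0.5, 2),
                     obs_noise_sd = 0.02,
                     merge_rule = c("sum", "mean"),
                     resize_filter = c("bilinear", "nearest"),
                     seed = 1L) {
  if (!(neg_fraction >= 0 && neg_fraction < 1)) {
    stop("sim_spec: neg_fraction must be in [0, 1)")
  }
  modes <- c("spatial", "trace", "both", "merged")
  if (is.null(names(mode_weights)) || !all(names(mode_weights) %in% modes)) {
    stop("sim_spec: mode_weights must be named over ", paste(modes, collapse = "/"))
  }
  w <- stats::setNames(numeric(4), modes)
  w[names(mode_weights)] <- mode_weights
  if (any(w < 0) || sum(w) == 0) {
    stop("sim_spec: mode_weights must be non-negative and not all zero")
  }
  if (any(spatial_factors <= 0) || any(spatial_factors == 1)) {
    stop("sim_spec: spatial_factors must be positive and != 1")
  }
  stopifnot(inherits(fov, "fov_geometry"), trace_noise_sd > 0,
            transient_rate >= 0, rise_frames > 0, decay_frames > rise_frames,
            footprint_radius > 0, obs_noise_sd >= 0)
  structure(
    list(n_rois = as.integer(n_rois), fov = fov,
         neg_fraction = neg_fraction, mode_weights = w,
         spatial_factors = spatial_factors, trace_noise_sd = trace_noise_sd,
         transient_rate = transient_rate, rise_frames = rise_frames,
         decay_frames = decay_frames, footprint_radius = footprint_radius,
         baseline_range = baseline_range, amp_range = amp_range,
         obs_noise_sd = obs_noise_sd, merge_rule = match.arg(merge_rule),
         resize_filter = match.arg(resize_filter), seed = as.integer(seed)),
    class = "sim_spec"
  )
}

# double-exponential calcium transient kernel, peak normalized to 1
calcium_kernel <- function(rise_frames, decay_frames) {
  stopifnot(rise_frames > 0, decay_frames > rise_frames)
  t <- 0:ceiling(6 * decay_frames)
  k <- exp(-t / decay_frames) - exp(-t / rise_frames)
  k / max(k)
}

# causal convolution of an event train with a kernel, truncated to length(ev)
convolve_events <- function(ev, kernel) {
  n <- length(ev)
  out <- stats::convolve(c(ev, numeric(length(kernel))), rev(kernel),
                         type = "open")
  out[seq_len(n)]
}

#' Simulate one positive (include-worthy) ROI
#'
#' Footprint: an anisotropic Gaussian blob of radius about `footprint_radius`,
#' random center, orientation and amplitude, thresholded to zero below 1e-3 of
#' its peak (source-extraction footprints are sparse). Trace: a constant
#' baseline plus Bernoulli-drawn transients convolved with a
#' double-exponential kernel, plus small Gaussian observation noise. The
#' number of simulated events is recorded in the ROI's `source` tag.
#'
#' @param spec A [sim_spec()].
#' @param id ROI identifier.
#' @param seed Optional integer; when given the ROI is a pure function of it.
#'   When `NULL` (default) the current RNG stream is consumed.
#' @return An [roi()] labeled `"include"`.
#' @export
simulate_positive_roi <- function(spec, id = "roi_00001", seed = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_positive_roi(spec, id)))
  }
  g <- spec$fov; r <- spec$footprint_radius
  if (4 * r > min(g$height, g$width)) {
    stop(sprintf("simulate_positive_roi: footprint_radius %g too large for %d x %d field of view",
                 r, g$height, g$width))
  }
  cy <- stats::runif(1, 2 * r, g$height - 2 * r)
  cx <- stats::runif(1, 2 * r, g$width - 2 * r)
  sy <- r / 2 * stats::runif(1, 0.75, 1.3)
  sx <- r / 2 * stats::runif(1, 0.75, 1.3)
  th <- stats::runif(1, 0, pi)
  amp <- stats::runif(1, 0.5, 1.5)
  yy <- matrix(seq_len(g$height), g$height, g$width)
  xx <- matrix(seq_len(g$width), g$height, g$width, byrow = TRUE)
  u <- (xx - cx) * cos(th) + (yy - cy) * sin(th)
  v <- -(xx - cx) * sin(th) + (yy - cy) * cos(th)
  fp <- amp * exp(-0.5 * ((u / sx)^2 + (v / sy)^2))
  fp[fp < 1e-3 * amp] <- 0

  n <- g$n_frames
  base <- stats::runif(1, spec$baseline_range[1], spec$baseline_range[2])
  onsets <- stats::rbinom(n, 1, spec$transient_rate)
  amps <- stats::runif(n, spec$amp_range[1], spec$amp_range[2])
  kernel <- calcium_kernel(spec$rise_frames, spec$decay_frames)
  trace <- base + convolve_events(onsets * amps, kernel) +
    stats::rnorm(n, 0, spec$obs_noise_sd)
  roi(id, fp, trace, label = "include",
      source = sprintf("simulated(events=%d)", sum(onsets)))
}

#' Corrupt an ROI by rescaling its footprint
#'
#' The footprint is resampled by `factor` (bilinear by default), thresholded
#' to zero below 1e-3 of its peak, and re-embedded in the original FOV with
#' the rescaled peak placed at the original peak position. The trace is
#' unchanged; the label becomes `"exclude"`.
#'
#' @param roi An [roi()].
#' @param factor Positive scale factor (1 is the identity and excluded from
#'   the default simulation set).
#' @param filter `"bilinear"` or `"nearest"`.
#' @return The corrupted [roi()].
#' @export
corrupt_spatial <- function(roi, factor, filter = c("bilinear", "nearest")) {
  stopifnot(inherits(roi, "roi"))
  filter <- match.arg(filter)
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0) {
    stop("corrupt_spatial: factor must be a single positive number")
  }
  roi$label <- "exclude"
  if (factor == 1) return(roi)
  fp <- roi$footprint
  pk <- peak_index(fp)
  hs <- max(1L, as.integer(round(nrow(fp) * factor)))
  ws <- max(1L, as.integer(round(ncol(fp) * factor)))
  s <- EBImage::resize(fp, w = hs, h = ws,
                       filter = if (filter == "nearest") "none" else "bilinear")
  s <- as.matrix(s)
  if (max(s) > 0) s[s < 1e-3 * max(s)] <- 0
  qk <- peak_index(pmax(s, 0))
  out <- matrix(0, nrow(fp), ncol(fp))
  # place s so its peak (qk) lands on the original peak (pk)
  r0 <- pk[1] - qk[1]; c0 <- pk[2] - qk[2]  # offsets
  rs_lo <- max(1L, 1L - r0); rs_hi <- min(hs, nrow(fp) - r0)
  cs_lo <- max(1L, 1L - c0); cs_hi <- min(ws, ncol(fp) - c0)
  if (rs_hi >= rs_lo && cs_hi >= cs_lo) {
    rs <- rs_lo:rs_hi; cs <- cs_lo:cs_hi
    out[rs + r0, cs + c0] <- s[rs, cs]
  }
  roi$footprint <- pmax(out, 0)
  roi
}

#' Corrupt an ROI by adding Gaussian noise to its trace
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation
#' `noise_sd * sd(trace)` framewise. For constant traces (sd 0) an absolute
#' noise floor of `noise_sd` is used and flagged via the
#' `"noise_absolute"` attribute of the result. Footprint unchanged; label
#' becomes `"exclude"`.
#'
#' @param roi An [roi()].
#' @param noise_sd Noise magnitude as a multiple of the trace sd (`> 0`).
#' @param seed Optional integer for a self-contained draw.
#' @return The corrupted [roi()].
#' @export
corrupt_trace <- function(roi, noise_sd, seed = NULL) {
  stopifnot(inherits(roi, "roi"))
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop("corrupt_trace: noise_sd must be > 0")
  }
  if (!is.null(seed)) return(withr::with_seed(seed, corrupt_trace(roi, noise_sd)))
  s <- stats::sd(roi$trace)
  absolute <- !is.finite(s) || s == 0
  sigma <- if (absolute) noise_sd else noise_sd * s
  roi$trace <- roi$trace + stats::rnorm(length(roi$trace), 0, sigma)
  roi$label <- "exclude"
  attr(roi, "noise_absolute") <- absolute
  roi
}

#' Corrupt an ROI spatially and temporally
#'
#' Composition of [corrupt_spatial()] and [corrupt_trace()]; the two act on
#' disjoint parts of the ROI, so the order is immaterial.
#'
#' @inheritParams corrupt_spatial
#' @inheritParams corrupt_trace
#' @return The corrupted [roi()].
#' @export
corrupt_both <- function(roi, factor, noise_sd,
                         filter = c("bilinear", "nearest"), seed = NULL) {
  corrupt_trace(corrupt_spatial(roi, factor, filter), noise_sd, seed = seed)
}

#' Corrupt by merging two ROIs into one
#'
#' Emulates source extraction incorrectly reporting two cells as a single
#' ROI: footprints are combined pixelwise and traces framewise, by sum
#' (default) or mean.
#'
#' @param roi_a,roi_b Two [roi()] objects with identical geometry.
#' @param rule `"sum"` or `"mean"`.
#' @return The merged [roi()], labeled `"exclude"`, carrying `roi_a`'s id and
#'   the partner id in the `"partner_id"` attribute.
#' @export
corrupt_merge <- function(roi_a, roi_b, rule = c("sum", "mean")) {
  stopifnot(inherits(roi_a, "roi"), inherits(roi_b, "roi"))
  rule <- match.arg(rule)
  if (!identical(dim(roi_a$footprint), dim(roi_b$footprint)) ||
      length(roi_a$trace) != length(roi_b$trace)) {
    stop("corrupt_merge: geometry mismatch between the two ROIs")
  }
  div <- if (rule == "mean") 2 else 1
  roi_a$footprint <- (roi_a$footprint + roi_b$footprint) / div
  roi_a$trace <- (roi_a$trace + roi_b$trace) / div
  roi_a$label <- "exclude"
  attr(roi_a, "partner_id") <- roi_b$id
  roi_a
}

#' Downsample a 2p-style ROI to emulate 1p data
#'
#' Block-averages the footprint by `spatial_factor` along each axis and
#' bin-averages the trace by `temporal_factor`; trailing rows/columns/frames
#' that do not fill a complete block are truncated. Mean fluorescence is
#' conserved up to that edge truncation.
#'
#' @param roi An [roi()].
#' @param spatial_factor,temporal_factor Integer downsampling factors
#'   (`>= 1`).
#' @return The downsampled [roi()] (label and id preserved).
#' @export
emulate_1p <- function(roi, spatial_factor = 1L, temporal_factor = 1L) {
  stopifnot(inherits(roi, "roi"))
  sf <- as.integer(spatial_factor); tf <- as.integer(temporal_factor)
  if (sf < 1L || tf < 1L) stop("emulate_1p: factors must be >= 1")
  fp <- roi$footprint
  if (sf > min(dim(fp))) {
    stop(sprintf("emulate_1p: spatial_factor %d exceeds footprint extent %d x %d",
                 sf, nrow(fp), ncol(fp)))
  }
  if (tf > length(roi$trace)) {
    stop(sprintf("emulate_1p: temporal_factor %d exceeds trace length %d",
                 tf, length(roi$trace)))
  }
  if (sf > 1L) {
    h2 <- nrow(fp) %/% sf; w2 <- ncol(fp) %/% sf
    a <- array(fp[seq_len(h2 * sf), seq_len(w2 * sf)], c(sf, h2, sf, w2))
    roi$footprint <- apply(a, c(2, 4), mean)
  }
  if (tf > 1L) {
    n2 <- length(roi$trace) %/% tf
    roi$trace <- colMeans(matrix(roi$trace[seq_len(n2 * tf)], tf, n2))
  }
  roi
}

#' Generate a simulated ground-truth dataset
#'
#' Draws `n_rois` positive ROIs, then corrupts exactly
#' `round(neg_fraction * n_rois)` of them into negatives, with corruption
#' modes sampled from `mode_weights`. Merged ROIs consume a sacrificial
#' partner generated for the purpose, so the positive count is unaffected.
#' The result is a pure function of the spec (including its seed).
#'
#' @param spec A [sim_spec()].
#' @return A list with `collection` (an `roi_collection`, every ROI labeled)
#'   and `records` (a data.frame with one row per ROI: `roi_id`, `mode` —
#'   `none` for positives — `factor`, `noise_sd`, `partner_id`,
#'   `noise_absolute`). `label == "exclude"` iff `mode != "none"`.
#' @export
make_simulated_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- spec$n_rois
  n_neg <- round(spec$neg_fraction * n)
  if (n < 2 && spec$mode_weights[["merged"]] > 0 && n_neg > 0) {
    stop("make_simulated_ground_truth: merged corruption needs n_rois >= 2")
  }
  withr::with_seed(spec$seed, {
    ids <- sprintf("roi_%05d", seq_len(n))
    rois <- lapply(seq_len(n), function(k) simulate_positive_roi(spec, ids[k]))
    records <- data.frame(
      roi_id = ids, mode = "none", factor = NA_real_, noise_sd = NA_real_,
      partner_id = NA_character_, noise_absolute = FALSE,
      stringsAsFactors = FALSE
    )
    if (n_neg > 0) {
      neg_idx <- sample(n, n_neg)
      modes <- sample(names(spec$mode_weights), n_neg, replace = TRUE,
                      prob = spec$mode_weights)
      for (j in seq_len(n_neg)) {
        k <- neg_idx[j]
        mode <- modes[j]
        rec <- records[k, ]
        out <- switch(
          mode,
          spatial = {
            f <- sample(spec$spatial_factors, 1)
            rec$factor <- f
            corrupt_spatial(rois[[k]], f, spec$resize_filter)
          },
          trace = {
            rec$noise_sd <- spec$trace_noise_sd
            corrupt_trace(rois[[k]], spec$trace_noise_sd)
          },
          both = {
            f <- sample(spec$spatial_factors, 1)
            rec$factor <- f
            rec$noise_sd <- spec$trace_noise_sd
            corrupt_both(rois[[k]], f, spec$trace_noise_sd, spec$resize_filter)
          },
          merged = {
            partner <- simulate_positive_roi(spec, paste0(ids[k], "_partner"))
            rec$partner_id <- partner$id
            corrupt_merge(rois[[k]], partner, spec$merge_rule)
          }
        )
        rec$mode <- mode
        rec$noise_absolute <- isTRUE(attr(out, "noise_absolute"))
        rois[[k]] <- out
        records[k, ] <- rec
      }
    }
    collection <- collect_rois(rois, spec$fov)
    collection$source <- ifelse(records$mode == "none", collection$source,
                                paste0("corrupted(", records$mode, ")"))
    list(collection = collection, records = records)
  })
}
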