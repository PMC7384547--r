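# Small-geometry fixtures used across the suite: a 32 x 32 px FOV with
# 120-frame traces keeps unit tests fast; the acceptance tests use the
# full-size defaults instead.

tiny_sim_spec <- function(n_rois = 60, seed = 7L, ...) {
  sim_spec(n_rois = n_rois,
           fov = fov_geometry(32, 32, 120, 5),
           footprint_radius = 3,
           seed = seed,
           ...)
}

tiny_preprocess <- function(modality = "combined") {
  preprocess_spec(crop_size = 16, trace_len = 100, modality = modality)
}

tiny_dataset <- function(n_rois = 60, seed = 7L, modality = "combined",
                         test_fraction = 0.2, ...) {
  gt <- make_simulated_ground_truth(tiny_sim_spec(n_rois, seed, ...))
  assemble_dataset(gt$collection, tiny_preprocess(modality),
                   test_fraction = test_fraction, seed = seed)
}

# a deterministic hand-made ROI: single bright blob, simple trace
blob_roi <- function(id = "r1", h = 10, w = 10, peak = c(5, 5), value = 5,
                     trace = seq_len(20)) {
  fp <- matrix(0, h, w)
  fp[peak[1], peak[2]] <- value
  roi(id, fp, trace)
}

# brute-force exhaustive segmentation search: the independent oracle for
# PELT. Enumerates all 2^(n-1) breakpoint subsets and returns the minimal
# objective (sum of within-segment SS + penalty per change point) and one
# optimal change-point set.
brute_force_segmentation <- function(x, penalty) {
  n <- length(x)
  ss <- function(v) sum((v - mean(v))^2)
  best <- list(cost = Inf, cps = integer(0))
  breaks <- if (n >= 2) 1:(n - 1) else integer(0)
  for (m in 0:length(breaks)) {
    combs <- if (m == 0) list(integer(0)) else utils::combn(breaks, m, simplify = FALSE)
    for (bp in combs) {
      starts <- c(1, bp + 1)
      ends <- c(bp, n)
      cost <- sum(vapply(seq_along(starts),
                         function(i) ss(x[starts[i]:ends[i]]), numeric(1))) +
        penalty * m
      if (cost < best$cost - 1e-12) best <- list(cost = cost, cps = bp + 1L)
    }
  }
  best
}

# objective value achieved by a given change-point set (1-based segment starts)
segmentation_cost <- function(x, cps, penalty) {
  starts <- c(1L, cps)
  ends <- c(cps - 1L, length(x))
  sum(vapply(seq_along(starts),
             function(i) {v <- x[starts[i]:ends[i]]; sum((v - mean(v))^2)},
             numeric(1))) + penalty * length(cps)
}
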