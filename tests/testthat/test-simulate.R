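test_that("positive ROIs have compact footprints and stable-baseline traces", {
  spec <- tiny_sim_spec(seed = 2)
  r <- simulate_positive_roi(spec, "a", seed = 10)
  expect_s3_class(r, "roi")
  expect_true(any(r$footprint > 0))
  expect_true(all(r$footprint >= 0))
  expect_equal(length(r$trace), 120)
  # no events + no observation noise -> constant baseline
  quiet <- sim_spec(n_rois = 1, fov = fov_geometry(32, 32, 120),
                    footprint_radius = 3, transient_rate = 0,
                    obs_noise_sd = 0, seed = 1)
  rq <- simulate_positive_roi(quiet, seed = 3)
  expect_equal(diff(range(rq$trace)), 0)
  # determinism
  expect_identical(simulate_positive_roi(spec, "a", seed = 10), r)
  expect_error(simulate_positive_roi(sim_spec(n_rois = 1, fov = fov_geometry(10, 10, 10),
                                              footprint_radius = 4, seed = 1)),
               "too large")
})

test_that("transient counts follow the configured event rate", {
  spec <- sim_spec(n_rois = 1, fov = fov_geometry(16, 16, 500),
                   footprint_radius = 2, transient_rate = 0.01, seed = 1)
  counts <- vapply(1:200, function(s) {
    r <- simulate_positive_roi(spec, seed = s)
    as.integer(sub(".*events=(\\d+).*", "\\1", r$source))
  }, integer(1))
  # binomial(500, 0.01): mean 5, se of the mean over 200 draws
  se <- sqrt(500 * 0.01 * 0.99 / 200)
  expect_lt(abs(mean(counts) - 5), 3 * se)
})

test_that("spatial corruption rescales the footprint area by ~factor^2", {
  spec <- tiny_sim_spec(seed = 6)
  r <- simulate_positive_roi(spec, seed = 20)
  a <- sum(r$footprint > 0)
  up <- corrupt_spatial(r, 2)
  expect_identical(up$label, "exclude")
  expect_identical(up$trace, r$trace)
  expect_gte(sum(up$footprint > 0), 3 * a)
  expect_lte(sum(up$footprint > 0), 5 * a)
  # identity of the rescaler at factor 1
  id <- corrupt_spatial(r, 1)
  expect_identical(id$footprint, r$footprint)
  expect_error(corrupt_spatial(r, -2), "positive")
  # downscaling shrinks support
  down <- corrupt_spatial(r, 1/2)
  expect_lt(sum(down$footprint > 0), a)
})

test_that("trace corruption adds Gaussian noise at the requested scale", {
  spec <- tiny_sim_spec(seed = 6)
  base <- sim_spec(n_rois = 1, fov = fov_geometry(16, 16, 500),
                   footprint_radius = 2, seed = 1)
  r <- simulate_positive_roi(base, seed = 30)
  out <- corrupt_trace(r, 2, seed = 31)
  expect_identical(out$footprint, r$footprint)
  expect_identical(out$label, "exclude")
  ratio <- sd(out$trace - r$trace) / sd(r$trace)
  expect_gt(ratio, 1.75)   # chi-square interval for sd at n = 500
  expect_lt(ratio, 2.25)
  expect_identical(corrupt_trace(r, 2, seed = 31), out)  # determinism
  # constant trace falls back to an absolute noise floor, flagged
  flat <- roi("f", r$footprint, rep(1, 500))
  out2 <- corrupt_trace(flat, 2, seed = 1)
  expect_true(attr(out2, "noise_absolute"))
  expect_gt(sd(out2$trace), 0)
  expect_error(corrupt_trace(r, 0), "noise_sd")
})

test_that("combined corruption commutes across the two disjoint parts", {
  spec <- tiny_sim_spec(seed = 6)
  r <- simulate_positive_roi(spec, seed = 40)
  ab <- corrupt_both(r, 2, 2, seed = 5)
  ba <- corrupt_spatial(corrupt_trace(r, 2, seed = 5), 2)
  expect_identical(ab$footprint, ba$footprint)
  expect_identical(ab$trace, ba$trace)
  expect_identical(ab$label, "exclude")
  # both component postconditions hold simultaneously
  a <- sum(r$footprint > 0)
  expect_gte(sum(ab$footprint > 0), 3 * a)
  expect_lte(sum(ab$footprint > 0), 5 * a)
  ratio <- sd(ab$trace - r$trace) / sd(r$trace)
  expect_gt(ratio, 1.75); expect_lt(ratio, 2.25)
})

test_that("merging sums footprints and traces", {
  a <- blob_roi("a", peak = c(2, 2), value = 3, trace = c(1, 2, 3))
  b <- blob_roi("b", peak = c(8, 8), value = 4, trace = c(10, 20, 30))
  m <- corrupt_merge(a, b)
  expect_identical(m$label, "exclude")
  expect_equal(attr(m, "partner_id"), "b")
  expect_equal(sum(m$footprint > 0), 2L)        # disjoint-support additivity
  expect_equal(m$trace, c(11, 22, 33))
  # additive identity with an all-zero partner
  z <- roi("z", matrix(0, 10, 10), c(0, 0, 0))
  m2 <- corrupt_merge(a, z)
  expect_identical(m2$footprint, a$footprint)
  expect_identical(m2$trace, a$trace)
  # support monotonicity
  expect_gte(sum(m$footprint > 0), max(sum(a$footprint > 0), sum(b$footprint > 0)))
  expect_error(corrupt_merge(a, blob_roi("c", h = 5, w = 5, peak = c(2, 2))),
               "geometry mismatch")
  # mean rule halves the disjoint sum
  expect_equal(corrupt_merge(a, b, rule = "mean")$trace, c(11, 22, 33) / 2)
})

test_that("1p emulation block-averages and conserves the mean", {
  r <- roi("r", matrix(2.5, 4, 4), c(1, 3, 5, 7))
  expect_identical(emulate_1p(r, 1, 1), r)
  d <- emulate_1p(r, 2, 2)
  expect_equal(d$footprint, matrix(2.5, 2, 2))
  expect_equal(d$trace, c(2, 6))
  set.seed(1)
  r2 <- roi("r2", matrix(runif(36), 6, 6), runif(12))
  d2 <- emulate_1p(r2, 3, 4)
  expect_equal(mean(d2$footprint), mean(r2$footprint))
  expect_equal(mean(d2$trace), mean(r2$trace))
  expect_error(emulate_1p(r, 5, 1), "exceeds")
  expect_error(emulate_1p(r, 1, 9), "exceeds")
})

test_that("ground-truth generation corrupts exactly the configured fraction", {
  gt <- make_simulated_ground_truth(tiny_sim_spec(n_rois = 200, seed = 12))
  expect_equal(sum(gt$collection$labels == "exclude"), round(0.15 * 200))
  # label bookkeeping: exclude <=> mode != none
  expect_identical(gt$collection$labels == "exclude", gt$records$mode != "none")
  expect_equal(nrow(gt$records), 200L)
  # merged records carry a partner id
  merged <- gt$records$mode == "merged"
  expect_true(all(!is.na(gt$records$partner_id[merged])))
  expect_true(all(is.na(gt$records$partner_id[!merged])))
  # neg_fraction 0: everything include / mode none
  gt0 <- make_simulated_ground_truth(tiny_sim_spec(n_rois = 20, seed = 12,
                                                   neg_fraction = 0))
  expect_true(all(gt0$collection$labels == "include"))
  expect_true(all(gt0$records$mode == "none"))
})

test_that("ground-truth generation is a pure function of the seed", {
  a <- make_simulated_ground_truth(tiny_sim_spec(n_rois = 30, seed = 99))
  b <- make_simulated_ground_truth(tiny_sim_spec(n_rois = 30, seed = 99))
  expect_identical(a$collection$footprints, b$collection$footprints)
  expect_identical(a$collection$traces, b$collection$traces)
  expect_identical(a$records, b$records)
  c_ <- make_simulated_ground_truth(tiny_sim_spec(n_rois = 30, seed = 100))
  expect_false(identical(a$collection$traces, c_$collection$traces))
})

test_that("corruption modes are drawn according to the mode weights", {
  counts <- sapply(1:20, function(s) {
    gt <- make_simulated_ground_truth(tiny_sim_spec(n_rois = 200, seed = 1000 + s))
    table(factor(gt$records$mode, levels = c("spatial", "trace", "both", "merged")))
  })
  # uniform weights over 4 modes, 30 corrupted per seed: expected 7.5 each;
  # se of the mean over 20 seeds of a multinomial cell count
  se <- sqrt(30 * 0.25 * 0.75 / 20)
  expect_true(all(abs(rowMeans(counts) - 7.5) < 3 * se))
  # spatial factors come from the configured set
  gt <- make_simulated_ground_truth(tiny_sim_spec(n_rois = 400, seed = 77))
  f <- gt$records$factor[!is.na(gt$records$factor)]
  expect_true(all(f %in% c(1/3, 1/2, 2, 3)))
  expect_error(make_simulated_ground_truth(
    sim_spec(n_rois = 1, fov = fov_geometry(32, 32, 50), footprint_radius = 3,
             neg_fraction = 0.9, seed = 1)), "merged corruption")
})
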