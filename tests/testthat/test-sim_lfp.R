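specs <- default_group_specs()

test_that("zero event rate yields an event-free trace", {
  spec <- group_spec("silent", baseline_rate_per_min = 0)
  sim <- generate_lfp(spec, seed = 1, fs = 200, phases = "baseline",
                      drift = FALSE)
  expect_identical(nrow(sim$ground_truth), 0L)
  expect_lt(max(abs(sim$trace$samples)), 0.5)  # noise stays subthreshold
})

test_that("generation is deterministic for a fixed seed", {
  a <- generate_lfp(specs$control, seed = 99, fs = 200, phases = "baseline")
  b <- generate_lfp(specs$control, seed = 99, fs = 200, phases = "baseline")
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$ground_truth, b$ground_truth)
  d <- generate_lfp(specs$control, seed = 100, fs = 200, phases = "baseline")
  expect_false(identical(a$trace$samples, d$trace$samples))
})

test_that("renewal process hits the requested rate within 3 SE", {
  # law of large numbers over 20 replicate baseline hours at 0.17/min
  counts <- vapply(1:20, function(s) {
    nrow(generate_lfp(specs$control, seed = 1000 + s, fs = 100,
                      phases = "baseline", drift = FALSE)$ground_truth)
  }, numeric(1))
  rate <- counts / specs$control$phase_durations_min[["baseline"]]
  se <- stats::sd(rate) / sqrt(length(rate))
  expect_lt(abs(mean(rate) - 0.17), 3 * se + 1e-9)
})

test_that("every generated SLE satisfies the detection criteria by construction", {
  sim <- generate_lfp(specs$control, seed = 7, fs = 200)
  gt <- sim$ground_truth
  expect_gt(nrow(gt), 5L)
  expect_true(all(gt$amplitude_mV >= 0.5))
  expect_true(all(gt$duration_s >= 10))
  # non-overlap with the 30 s refractory gap
  ord <- gt[order(gt$onset_s), ]
  gaps <- utils::head(ord$onset_s[-1] - (ord$onset_s + ord$duration_s)[-nrow(ord)], -1)
  expect_true(all(ord$onset_s[-1] - (ord$onset_s + ord$duration_s)[-nrow(ord)]
                  >= 30 - 1e-9))
  expect_true(all(gt$onset_s >= 0 &
                    gt$onset_s + gt$duration_s <=
                      length(sim$trace$samples) / sim$trace$fs))
})

test_that("invalid generator inputs are rejected", {
  expect_error(generate_lfp(specs$control, seed = 1, fs = 0), "positive")
  expect_error(generate_lfp(specs$control, seed = 1, fs = -5), "positive")
  expect_error(generate_cohort(specs$control, n_slices = 0, seed = 1),
               "n_slices")
  # rate incompatible with the refractory dead time
  spec <- group_spec("fast", baseline_rate_per_min = 0.9,
                     duration_mean_s = c(53, 53, 53))
  expect_error(generate_lfp(spec, seed = 1, fs = 100, phases = "baseline"),
               "refractory")
})

test_that("cohorts are reproducible with distinct per-slice seeds", {
  a <- generate_cohort(specs$control, n_slices = 3, seed = 5, fs = 100,
                       phases = "baseline")
  b <- generate_cohort(specs$control, n_slices = 3, seed = 5, fs = 100,
                       phases = "baseline")
  expect_identical(lapply(a, function(x) x$trace$samples),
                   lapply(b, function(x) x$trace$samples))
  expect_length(unique(vapply(a, function(x) x$slice_id, "")), 3L)
  # slices differ from one another
  expect_false(identical(a[[1]]$trace$samples, a[[2]]$trace$samples))
})
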