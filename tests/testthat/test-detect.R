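specs <- default_group_specs()

test_that("remove_drift flattens slow wander and preserves DC shifts", {
  fs <- 200
  # flat trace + linear drift -> flat (window chosen below the trace span)
  tr <- lfp_trace(seq(0, 1.5, length.out = 600 * fs), fs)
  out <- remove_drift(tr, cutoff_hz = 1 / 150)
  expect_length(out$samples, length(tr$samples))
  mid <- out$samples[(100 * fs):(500 * fs)]
  expect_lt(max(abs(mid)), 0.06)

  # synthetic SLE plateau of 0.8 mV survives correction within 5%
  x <- numeric(600 * 500)
  x <- apseize:::add_sle_waveform(x, 500, 300, 50, 0.8, 140)
  x <- x + seq(0, 1.0, length.out = length(x))  # drift on top
  tr2 <- remove_drift(lfp_trace(x, 500), cutoff_hz = 1 / 150)
  ev <- detect_sles(tr2)
  expect_identical(nrow(ev), 1L)
  expect_close(ev$dc_shift_mV, 0.8, rel = 0.05)

  expect_error(lfp_trace(numeric(0), fs), "zero-length")
  expect_error(remove_drift(lfp_trace(rnorm(100), 100), cutoff_hz = 60),
               "Nyquist")
})

test_that("criteria boundaries reject undersized deflections", {
  fs <- 500
  # 0.4 mV for 60 s: fails the amplitude criterion
  t1 <- make_test_trace(120, 60, 0.4, total_s = 300, fs = fs, seed = 2)
  expect_identical(nrow(detect_sles(t1)), 0L)
  # 1.0 mV for 8 s: fails the duration criterion
  t2 <- make_test_trace(120, 8, 1.0, total_s = 300, fs = fs, seed = 3)
  expect_identical(nrow(detect_sles(t2)), 0L)
  # 1.0 mV for 60 s: accepted
  t3 <- make_test_trace(120, 60, 1.0, total_s = 300, fs = fs, seed = 4)
  ev <- detect_sles(t3)
  expect_identical(nrow(ev), 1L)
  expect_true(ev$ripple_confirmed)
  expect_close(ev$onset_s, 120, abs = 1)
  expect_error(detect_sles(lfp_trace(c(1, NA, 3), 100)), "non-finite")
})

test_that("detection is invariant to a constant offset", {
  tr <- make_test_trace(c(60, 180), c(40, 55), c(1.2, 0.9),
                        total_s = 300, seed = 5)
  ev0 <- detect_sles(tr)
  tr$samples <- tr$samples + 17.3
  ev1 <- detect_sles(tr)
  expect_equal(ev0, ev1)
})

test_that("detector matches the brute-force oracle on short traces", {
  set.seed(42)
  for (rep in 1:6) {
    n_ev <- sample(0:2, 1)
    onsets <- sort(runif(n_ev, 30, 220))
    if (n_ev == 2 && diff(onsets) < 100) onsets[2] <- onsets[1] + 100
    durs <- runif(n_ev, 15, 60)
    amps <- runif(n_ev, 0.7, 2)
    tr <- make_test_trace(onsets, durs, amps, total_s = 300, seed = 100 + rep)
    got <- detect_sles(tr)
    want <- oracle_detect(tr)
    expect_identical(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_true(all(abs(got$onset_s - want$onset) <= 1))
      expect_true(all(abs(got$offset_s - want$offset) <= 1.5))
    }
  }
})

test_that("no false positives on pure-noise traces over 100 seeds", {
  hits <- vapply(1:100, function(s) {
    tr <- make_test_trace(numeric(0), numeric(0), numeric(0),
                          total_s = 180, seed = s)
    nrow(detect_sles(tr))
  }, numeric(1))
  expect_identical(sum(hits), 0)
})

test_that("generator and detector agree on a control slice", {
  sim <- generate_lfp(specs$control, seed = 31, fs = 500)
  ev <- detect_sles(remove_drift(sim$trace))
  gt <- sim$ground_truth[order(sim$ground_truth$onset_s), ]
  expect_identical(nrow(ev), nrow(gt))
  expect_true(all(abs(ev$onset_s - gt$onset_s) <= 1))
  expect_true(all(abs(ev$dc_shift_mV - gt$amplitude_mV) < 0.15))
  expect_identical(ev$phase, gt$phase)
})

test_that("slice inclusion follows the 45-min rule", {
  ev <- function(onset_min) data.frame(onset_s = onset_min * 60)
  expect_true(check_slice_inclusion(ev(44)))
  expect_false(check_slice_inclusion(ev(46)))
  expect_false(check_slice_inclusion(data.frame(onset_s = numeric(0))))
  # measured from the 4-AP start, not from zero
  expect_true(check_slice_inclusion(ev(50), fourAP_start_s = 10 * 60))
})

test_that("phase summaries use full-window frequency and last-k means", {
  evs <- data.frame(onset_s = seq(100, 2200, length.out = 6),
                    offset_s = NA, duration_s = 41:46,
                    dc_shift_mV = seq(1, 2, length.out = 6),
                    ripple_confirmed = TRUE, phase = "baseline")
  w <- list(phase = "baseline", start_s = 0, end_s = 2400)
  s <- summarize_phase(evs, w, k = 5)
  expect_equal(s$sle_frequency_per_min, 6 / 40)  # 0.15 min^-1
  expect_equal(s$n_events_analyzed, 5L)
  expect_equal(s$mean_duration_s, mean(42:46))   # last five only
  s3 <- summarize_phase(evs, w, k = 3)
  expect_equal(s3$mean_dc_shift_mV, mean(seq(1, 2, length.out = 6)[4:6]))

  empty <- summarize_phase(evs[0, ], w)
  expect_equal(empty$sle_frequency_per_min, 0)
  expect_identical(empty$n_events_analyzed, 0L)
  expect_true(is.na(empty$mean_duration_s))

  expect_error(summarize_phase(evs, list(phase = "x", start_s = 10,
                                         end_s = 5)), "invalid")
  expect_error(summarize_phase(evs, w, k = 6), "between 3 and 5")
})

test_that("lower intervention rates never increase detected frequency", {
  freq_at <- function(ratio, seeds) {
    mean(vapply(seeds, function(s) {
      spec <- group_spec("dose", rate_ratio_intervention = ratio,
                         phase_durations_min = c(40, 40, 40))
      sim <- generate_lfp(spec, seed = s, fs = 250,
                          phases = c("baseline", "intervention"))
      ev <- detect_sles(remove_drift(sim$trace))
      summarize_phase(ev, sim$trace$phases[2, ])$sle_frequency_per_min
    }, numeric(1)))
  }
  expect_lte(freq_at(0.2, 1:4), freq_at(0.9, 1:4))
})
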