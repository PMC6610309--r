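PHASES <- c("baseline", "intervention", "washout")

mk_summary <- function(fb, fi, fw, db = 50, di = 50, dw = 50,
                       ab = 1.6, ai = 1.6, aw = 1.6) {
  data.frame(phase = c("baseline", "intervention", "washout"),
             sle_frequency_per_min = c(fb, fi, fw),
             mean_duration_s = c(db, di, dw),
             mean_dc_shift_mV = c(ab, ai, aw))
}

test_that("slice effects: ratios and the 50% responder boundary", {
  e <- compute_slice_effects(mk_summary(0.16, 0.08, 0.15))
  expect_equal(e$frequency_ratio, 0.5)
  expect_true(e$responder)            # >= 50% reduction, boundary inclusive

  e2 <- compute_slice_effects(mk_summary(0.16, 0, 0.12))
  expect_identical(e2$frequency_ratio, 0)
  expect_true(e2$responder)

  e3 <- compute_slice_effects(mk_summary(0.16, 0.12, 0.15))
  expect_equal(e3$frequency_ratio, 0.75)
  expect_false(e3$responder)

  expect_error(compute_slice_effects(mk_summary(0, 0, 0)), "inclusion")

  # IOS ratios, with full-block missingness kept as NA
  ios <- data.frame(phase = c("baseline", "intervention"),
                    region = "SUB", dtt_pct = c(1.1, 0.38),
                    area_pct = c(58.9, NA))
  e4 <- compute_slice_effects(mk_summary(0.16, 0.1, 0.14), ios = ios)
  expect_equal(e4$dtt_ratio_SUB, 0.38 / 1.1)
  expect_true(is.na(e4$area_ratio_SUB))
})

test_that("responder_rate counts all slices and ignores ordering", {
  flags <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(responder_rate(flags), 0.5)
  expect_equal(responder_rate(rev(flags)), 0.5)
  expect_equal(responder_rate(rep(TRUE, 5)), 1)
  expect_equal(responder_rate(rep(FALSE, 3)), 0)
  expect_error(responder_rate(logical(0)), "no slices")
})

test_that("within-group test: null, effect, and full-block branches", {
  # identical values across phases -> p ~ 1
  d0 <- data.frame(slice_id = rep(1:6, each = 3),
                   phase = rep(PHASES, 6),
                   value = rep(0.15, 18))
  r0 <- within_group_test(d0)
  expect_true(all(r0$contrasts$p > 0.99))

  # full block: paired t-test baseline vs wash-out
  set.seed(8)
  db <- data.frame(slice_id = rep(1:5, each = 3), phase = rep(PHASES, 5),
                   value = rep(c(0.17, 0, 0.15), 5) +
                     runif(15, -0.02, 0.02) * rep(c(1, 0, 1), 5))
  rb <- within_group_test(db)
  expect_match(rb$method, "full block")
  expect_identical(nrow(rb$contrasts), 1L)

  expect_error(within_group_test(d0[1:6, ]), "at least 3")
})

test_that("within-group test detects the lacosamide-scale effect reliably", {
  # power check on simulated effect sizes: 10 slices, ratio 0.54
  hits <- vapply(1:10, function(rep) {
    cohort <- generate_cohort(default_group_specs()$LAC_33, n_slices = 10,
                              seed = 500 + rep, fs = 40, drift = FALSE)
    d <- do.call(rbind, lapply(cohort, function(ex) {
      counts <- table(factor(ex$ground_truth$phase,
                             c("baseline", "intervention", "washout")))
      data.frame(slice_id = ex$slice_id,
                 phase = names(counts),
                 value = as.numeric(counts) / 60)
    }))
    r <- within_group_test(d)
    r$contrasts$p[r$contrasts$contrast == "intervention - baseline"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("between-group test: errors, null calibration, extreme power", {
  expect_error(between_group_test(data.frame(group = "a", value = 1:5)),
               "two groups")
  expect_error(between_group_test(data.frame(group = rep(c("a", "b"), 4),
                                             value = rnorm(8))),
               "control")

  # type-I error under the null ~ alpha (omnibus ANOVA), 500 replicates
  set.seed(11)
  rejections <- vapply(1:500, function(i) {
    d <- data.frame(group = rep(c("control", "g1", "g2"), each = 8),
                    value = rnorm(24, 1, 0.2))
    between_group_test(d)$omnibus_p < 0.05
  }, logical(1))
  p_hat <- mean(rejections)
  se <- sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(p_hat - 0.05), 2 * se + 1e-9)

  # control vs full block: essentially always significant after FDR
  set.seed(12)
  sig <- vapply(1:100, function(i) {
    d <- data.frame(
      group = c(rep("control", 22), rep("blocked", 5)),
      value = c(pmax(rnorm(22, 0.9, 0.12), 0), rep(0, 5)))
    between_group_test(d)$vs_control$p_adj[1] < 0.05
  }, logical(1))
  expect_gte(mean(sig), 0.95)
})

test_that("baseline-effect correlation: analytic and null behaviour", {
  # perfectly proportional effect: ratio = c * baseline -> r = 1
  b <- seq(0.1, 0.3, length.out = 10)
  expect_equal(baseline_effect_correlation(b, 2 * b)$r, 1)
  expect_equal(baseline_effect_correlation(b, 1 - b)$r, -1)
  expect_error(baseline_effect_correlation(c(1, 2), c(3, 4)), "at least 3")

  # independent ratio: p roughly uniform, |r| small on average
  set.seed(13)
  stats <- t(vapply(1:200, function(i) {
    r <- baseline_effect_correlation(rnorm(15, 0.17, 0.03),
                                     rnorm(15, 0.6, 0.1))
    c(r = r$r, p = r$p)
  }, numeric(2)))
  expect_lt(abs(mean(stats[, "r"])), 0.08)
  expect_lt(abs(mean(stats[, "p"]) - 0.5), 0.07)
})

test_that("group summaries conserve the per-slice tables", {
  set.seed(14)
  eff <- do.call(rbind, lapply(1:8, function(i)
    compute_slice_effects(mk_summary(runif(1, 0.1, 0.2), runif(1, 0, 0.15),
                                     runif(1, 0.05, 0.2)),
                          slice_id = i, group_label = "g")))
  g <- group_result(eff)
  expect_equal(unname(g$frequency_ratio["mean"]), mean(eff$frequency_ratio))
  expect_equal(unname(g$frequency_ratio["sd"]), sd(eff$frequency_ratio))
  expect_equal(g$responder_rate, mean(eff$responder))
  expect_identical(g$n_slices, nrow(eff))
})
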