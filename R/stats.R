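# Drug-effect aggregation: ratios, responder rates, within/between-group tests.

#' Per-slice drug-effect measures
#'
#' Turns a slice's three phase summaries (and optionally per-phase regional
#' IOS summaries) into effect ratios: intervention / baseline for SLE
#' frequency, duration, DC-shift amplitude and, per region, dT/T and area.
#' The responder flag marks a frequency reduction of at least 50%
#' (`frequency_ratio <= 0.5`); a full block gives a ratio of exactly 0.
#' Undefined IOS ratios (no SLE to image during a full block) are `NA`.
#'
#' @param summary data.frame with one row per phase (from [summarize_trace]):
#'   columns `phase`, `sle_frequency_per_min`, `mean_duration_s`,
#'   `mean_dc_shift_mV`.
#' @param ios optional data.frame with columns `phase`, `region`, `dtt_pct`,
#'   `area_pct`.
#' @param slice_id,group_label identifiers carried through.
#' @return one-row data.frame of class `slice_effect`.
#' @export
compute_slice_effects <- function(summary, ios = NULL, slice_id = NA_character_,
                                  group_label = NA_character_) {
  gv <- function(ph, col) {
    v <- summary[[col]][summary$phase == ph]
    if (length(v) != 1L) NA_real_ else v
  }
  fb <- gv("baseline", "sle_frequency_per_min")
  if (is.na(fb) || fb <= 0)
    stop("baseline SLE frequency is 0: slice violates the 45-min inclusion ",
         "rule and must be excluded before effect computation")
  ratio <- function(col) {
    b <- gv("baseline", col); i <- gv("intervention", col)
    if (is.na(b) || is.na(i) || b == 0) NA_real_ else i / b
  }
  fr <- gv("intervention", "sle_frequency_per_min") / fb
  out <- data.frame(
    slice_id = slice_id, group_label = group_label,
    baseline_frequency_per_min = fb,
    baseline_duration_s = gv("baseline", "mean_duration_s"),
    baseline_dc_shift_mV = gv("baseline", "mean_dc_shift_mV"),
    frequency_ratio = fr,
    washout_frequency_ratio =
      gv("washout", "sle_frequency_per_min") / fb,
    duration_ratio = ratio("mean_duration_s"),
    amplitude_ratio = ratio("mean_dc_shift_mV"),
    responder = !is.na(fr) && fr <= 0.5)
  if (!is.null(ios)) {
    for (r in unique(ios$region)) {
      b <- ios[ios$phase == "baseline" & ios$region == r, , drop = FALSE]
      i <- ios[ios$phase == "intervention" & ios$region == r, , drop = FALSE]
      rr <- function(col)
        if (nrow(b) == 1L && nrow(i) == 1L && !is.na(b[[col]]) &&
            !is.na(i[[col]]) && b[[col]] != 0) i[[col]] / b[[col]] else NA_real_
      out[[paste0("dtt_ratio_", r)]] <- rr("dtt_pct")
      out[[paste0("area_ratio_", r)]] <- rr("area_pct")
    }
  }
  class(out) <- c("slice_effect", "data.frame")
  out
}

#' Responder rate of a group
#'
#' Fraction of slices with a frequency reduction of at least 50% during
#' intervention, counting every investigated slice in the denominator.
#'
#' @param effects data.frame with a logical `responder` column (rbind of
#'   [compute_slice_effects] rows), or a logical vector.
#' @return fraction in \[0, 1\].
#' @export
responder_rate <- function(effects) {
  flags <- if (is.data.frame(effects)) effects$responder else effects
  if (length(flags) == 0L) stop("no slices")
  mean(flags)
}

#' Within-group repeated-measures comparison
#'
#' Fits a linear mixed-effects model `value ~ phase + (1 | slice)` across the
#' three repeated measurements and reports Tukey-adjusted pairwise phase
#' contrasts (studentized-range adjustment on the model's contrast
#' t-statistics, with classical repeated-measures df `(n-1)(k-1)`). When the
#' intervention phase has no usable values in any slice (full SLE block), the
#' model degenerates and a two-sided paired t-test between baseline and
#' wash-out is substituted. If the mixed model fails to fit on small n, a
#' Bonferroni-adjusted paired t-test fallback is used.
#'
#' @param data data.frame with columns `slice_id`, `phase`, `value`
#'   (one row per slice and phase).
#' @return list with `method` and `contrasts` (data.frame: `contrast`,
#'   `estimate`, `p`).
#' @export
within_group_test <- function(data) {
  stopifnot(all(c("slice_id", "phase", "value") %in% names(data)))
  n <- length(unique(data$slice_id))
  if (n < 3L) stop("need at least 3 slices")
  phs <- intersect(PHASES, unique(data$phase))
  if (length(phs) < 2L) stop("need at least two phases")
  iv <- data$value[data$phase == "intervention"]
  full_block <- length(iv) == 0L || all(is.na(iv)) ||
    (all(iv == 0) && any(data$value[data$phase == "baseline"] > 0))
  if (full_block) {
    b <- data$value[data$phase == "baseline"][order(data$slice_id[data$phase == "baseline"])]
    w <- data$value[data$phase == "washout"][order(data$slice_id[data$phase == "washout"])]
    tt <- safe_paired_t(w, b)
    return(list(method = "paired t-test (full block): baseline vs wash-out",
                contrasts = data.frame(
                  contrast = "washout - baseline",
                  estimate = tt$estimate, p = tt$p)))
  }
  data$phase <- factor(data$phase, levels = phs)
  data$slice_id <- factor(data$slice_id)
  k <- length(phs)
  df_rm <- (n - 1L) * (k - 1L)
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(value ~ phase + (1 | slice_id), data = data,
                 control = lme4::lmerControl(check.conv.singular =
                                               lme4::.makeCC("ignore", 1e-4))))),
    error = function(e) NULL)
  pairs <- utils::combn(phs, 2L, simplify = FALSE)
  if (is.null(fit)) {
    ct <- do.call(rbind, lapply(pairs, function(pr) {
      a <- data$value[data$phase == pr[1L]][order(data$slice_id[data$phase == pr[1L]])]
      b <- data$value[data$phase == pr[2L]][order(data$slice_id[data$phase == pr[2L]])]
      tt <- safe_paired_t(b, a)
      data.frame(contrast = paste(pr[2L], "-", pr[1L]),
                 estimate = tt$estimate, p = tt$p)
    }))
    ct$p <- pmin(1, ct$p * length(pairs))
    return(list(method = "paired t-tests, Bonferroni (lmer fallback)",
                contrasts = ct))
  }
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  ct <- do.call(rbind, lapply(pairs, function(pr) {
    cvec <- stats::setNames(numeric(length(beta)), names(beta))
    for (s in c(1L, 2L)) {
      nm <- paste0("phase", pr[s])
      sgn <- if (s == 1L) -1 else 1
      if (nm %in% names(cvec)) cvec[nm] <- cvec[nm] + sgn
      # reference level contributes only the intercept, which cancels
    }
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    scale_eps <- 1e-9 * max(1, abs(beta[1L]))
    tval <- if (se > scale_eps || abs(est) > scale_eps) est / max(se, scale_eps)
    else 0
    p <- stats::ptukey(sqrt(2) * abs(tval), nmeans = k, df = df_rm,
                       lower.tail = FALSE)
    data.frame(contrast = paste(pr[2L], "-", pr[1L]), estimate = est, p = p)
  }))
  list(method = sprintf(
    "linear mixed model (random slice intercept), Tukey df=%d", df_rm),
    contrasts = ct)
}

# paired t that degrades gracefully when the differences are constant:
# zero difference -> p = 1 (no effect), constant non-zero -> p -> 0
safe_paired_t <- function(b, a) {
  d <- b - a
  if (stats::sd(d) < 1e-12 * max(1, abs(mean(d)))) {
    return(list(estimate = mean(d),
                p = if (abs(mean(d)) < 1e-12) 1 else .Machine$double.eps))
  }
  tt <- stats::t.test(b, a, paired = TRUE)
  list(estimate = unname(tt$estimate), p = tt$p.value)
}

#' Between-group comparison of effect ratios
#'
#' One-way ANOVA across all groups, followed by pairwise Welch t-tests of
#' each drug group against the control group only, with
#' Benjamini-Hochberg-Yekutieli false-discovery-rate adjustment.
#'
#' @param data data.frame with columns `group` and `value` (one row per
#'   slice).
#' @param control label of the control group (default `"control"`).
#' @return list with `omnibus_p` and `vs_control` (data.frame: `group`,
#'   `p_raw`, `p_adj`).
#' @export
between_group_test <- function(data, control = "control") {
  stopifnot(all(c("group", "value") %in% names(data)))
  data <- data[!is.na(data$value), , drop = FALSE]
  groups <- unique(data$group)
  if (length(groups) < 2L) stop("need at least two groups")
  if (!control %in% groups) stop("control group not present")
  fit <- stats::aov(value ~ group, data = data)
  omnibus_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
  others <- setdiff(groups, control)
  p_raw <- vapply(others, function(g) {
    stats::t.test(data$value[data$group == g],
                  data$value[data$group == control])$p.value
  }, numeric(1))
  list(omnibus_p = omnibus_p,
       vs_control = data.frame(group = others, p_raw = unname(p_raw),
                               p_adj = stats::p.adjust(p_raw, "BY")))
}

#' Baseline-vs-effect correlation
#'
#' Pearson correlation between a baseline metric and its relative
#' intervention effect (intervention / baseline ratio), with two-sided p.
#'
#' @param baseline numeric vector of per-slice baseline values.
#' @param ratio numeric vector of per-slice intervention/baseline ratios.
#' @return list with `r`, `p`, `n`.
#' @export
baseline_effect_correlation <- function(baseline, ratio) {
  keep <- is.finite(baseline) & is.finite(ratio)
  if (sum(keep) < 3L) stop("need at least 3 complete pairs for a p-value")
  ct <- stats::cor.test(baseline[keep], ratio[keep], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}

#' Aggregate per-slice effects into a group result
#'
#' @param effects data.frame of [compute_slice_effects] rows for one group.
#' @param phase_values optional long data.frame (`slice_id`, `phase`,
#'   `value`) of per-phase frequencies for the within-group test.
#' @return list of class `group_result`.
#' @export
group_result <- function(effects, phase_values = NULL) {
  stopifnot(nrow(effects) >= 1L)
  msd <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = stats::sd(v, na.rm = TRUE))
  res <- list(
    group_label = effects$group_label[1L],
    n_slices = nrow(effects),
    frequency_ratio = msd(effects$frequency_ratio),
    washout_frequency_ratio = msd(effects$washout_frequency_ratio),
    duration_ratio = msd(effects$duration_ratio),
    amplitude_ratio = msd(effects$amplitude_ratio),
    responder_rate = responder_rate(effects))
  if (!is.null(phase_values) && length(unique(phase_values$slice_id)) >= 3L)
    res$within_group <- within_group_test(phase_values)
  class(res) <- "group_result"
  res
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group_result> %s: n=%d, frequency ratio %.3f +/- %.3f, responders %.0f%%\n",
              x$group_label, x$n_slices, x$frequency_ratio["mean"],
              x$frequency_ratio["sd"], 100 * x$responder_rate))
  invisible(x)
}

#' Write summary tables and figures for a cohort
#'
#' Emits `group_summary.csv` (one row per group: n, ratio mean/SD, responder
#' rate, within-group p), a frequency-ratio scatter plot, a per-phase
#' frequency plot (scatter + mean +/- SD), and a responder-rate bar chart as
#' PNG files.
#'
#' @param groups named list of `group_result` objects.
#' @param effects_all data.frame of all slice effects (for the scatters).
#' @param out_dir output directory.
#' @param phase_freq optional long data.frame (`group`, `slice_id`, `phase`,
#'   `value`) of per-phase frequencies.
#' @return invisible path of the summary CSV.
#' @export
build_report <- function(groups, effects_all, out_dir, phase_freq = NULL) {
  if (length(groups) == 0L) stop("empty group list")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- do.call(rbind, lapply(groups, function(g) data.frame(
    group = g$group_label, n_slices = g$n_slices,
    frequency_ratio_mean = unname(g$frequency_ratio["mean"]),
    frequency_ratio_sd = unname(g$frequency_ratio["sd"]),
    responder_rate = g$responder_rate,
    p_intervention_vs_baseline = within_p(g, "intervention - baseline"),
    p_washout_vs_baseline = within_p(g, "washout - baseline"))))
  csv <- file.path(out_dir, "group_summary.csv")
  utils::write.csv(tab, csv, row.names = FALSE)

  ord <- tab$group
  grDevices::png(file.path(out_dir, "frequency_ratio_scatter.png"),
                 900, 500)
  graphics::par(mar = c(7, 4, 2, 1))
  gi <- match(effects_all$group_label, ord)
  graphics::plot(jitter(gi, 0.2), effects_all$frequency_ratio, xaxt = "n",
                 xlab = "", ylab = "SLE frequency ratio (intervention/baseline)",
                 pch = 19, col = "#00000080",
                 xlim = c(0.5, length(ord) + 0.5))
  graphics::axis(1, at = seq_along(ord), labels = ord, las = 2)
  graphics::points(seq_along(ord), tab$frequency_ratio_mean, pch = 3,
                   col = "red", cex = 2)
  grDevices::dev.off()

  grDevices::png(file.path(out_dir, "responder_rate.png"), 900, 400)
  graphics::par(mar = c(7, 4, 2, 1))
  graphics::barplot(tab$responder_rate, names.arg = ord, las = 2,
                    ylim = c(0, 1), ylab = "responder rate")
  grDevices::dev.off()

  if (!is.null(phase_freq)) {
    grDevices::png(file.path(out_dir, "phase_frequency.png"), 1000, 500)
    graphics::par(mar = c(7, 4, 2, 1))
    phase_freq$xi <- match(phase_freq$group, ord) +
      (match(phase_freq$phase, PHASES) - 2) * 0.22
    graphics::plot(phase_freq$xi, phase_freq$value, pch = 19,
                   col = c(baseline = "#1b9e77", intervention = "#d95f02",
                           washout = "#7570b3")[phase_freq$phase],
                   xaxt = "n", xlab = "",
                   ylab = "SLE frequency (1/min)",
                   xlim = c(0.5, length(ord) + 0.5))
    graphics::axis(1, at = seq_along(ord), labels = ord, las = 2)
    agg <- stats::aggregate(value ~ group + phase, phase_freq, mean)
    agg$xi <- match(agg$group, ord) + (match(agg$phase, PHASES) - 2) * 0.22
    graphics::points(agg$xi, agg$value, pch = 3, cex = 2)
    grDevices::dev.off()
  }
  invisible(csv)
}

within_p <- function(g, contrast) {
  wg <- g$within_group
  if (is.null(wg)) return(NA_real_)
  i <- match(contrast, wg$contrasts$contrast)
  if (is.na(i)) {
    if (grepl("full block", wg$method) && contrast == "washout - baseline")
      return(wg$contrasts$p[1L])
    return(NA_real_)
  }
  wg$contrasts$p[i]
}
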