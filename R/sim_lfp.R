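# Synthetic local field potential traces with known SLE ground truth.

#' Construct an LFP trace object
#'
#' @param samples numeric vector, voltage in mV.
#' @param fs sampling rate in Hz (> 0).
#' @param phases data.frame with columns `phase`, `start_s`, `end_s`;
#'   ordered, non-overlapping, within the trace span.
#' @param metadata named list (slice/animal IDs, group label, viability flag).
#' @return object of class `lfp_trace`.
#' @export
lfp_trace <- function(samples, fs, phases = NULL, metadata = list()) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("sampling rate must be a single positive number")
  if (length(samples) == 0L) stop("zero-length trace")
  span <- length(samples) / fs
  if (!is.null(phases)) {
    stopifnot(all(c("phase", "start_s", "end_s") %in% names(phases)))
    if (any(phases$end_s <= phases$start_s) ||
        any(diff(phases$start_s) <= 0) ||
        any(utils::head(phases$end_s, -1) > utils::tail(phases$start_s, -1) + 1e-9) ||
        max(phases$end_s) > span + 1e-6)
      stop("phase windows must be ordered, non-overlapping and inside the trace")
  }
  structure(list(samples = samples, fs = fs, phases = phases,
                 metadata = metadata),
            class = "lfp_trace")
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("<lfp_trace> %.1f min @ %g Hz (%d samples)\n",
              length(x$samples) / x$fs / 60, x$fs, length(x$samples)))
  if (!is.null(x$phases))
    cat(sprintf("  phases: %s\n",
                paste(sprintf("%s [%g, %g) s", x$phases$phase,
                              x$phases$start_s, x$phases$end_s),
                      collapse = ", ")))
  invisible(x)
}

# Event trains are renewal processes: a refractory dead time (event duration
# + 30 s) followed by a random gap. The gap is Gamma(shape = 4) rather than
# exponential: recorded SLEs recur quasi-periodically, and with exponential
# gaps the counting noise alone would exceed the published between-slice
# frequency SD (0.03 min^-1), making that spread unreproducible.
GAP_SHAPE <- 4

draw_gap <- function(n, lam) stats::rgamma(n, shape = GAP_SHAPE,
                                           rate = GAP_SHAPE * lam)

# Delay from a phase start to the first onset, drawn from the equilibrium
# forward-recurrence distribution of the interval law (dead time + gamma
# gap). The SLE train is already running when a phase begins, so starting in
# the stationary regime keeps E[count] = window / mean-interval exactly; an
# ordinary-renewal start would undercount by (1 - CV^2)/2 events per phase.
eq_first_delay <- function(lam, dead_s) {
  mu <- dead_s + 1 / lam
  tmax <- dead_s + stats::qgamma(0.9999, GAP_SHAPE, rate = GAP_SHAPE * lam)
  tg <- seq(0, tmax, length.out = 512L)
  S <- ifelse(tg < dead_s, 1,
              1 - stats::pgamma(tg - dead_s, GAP_SHAPE,
                                rate = GAP_SHAPE * lam))
  Fe <- c(0, cumsum((S[-1L] + S[-length(S)]) / 2 * diff(tg)) / mu)
  u <- stats::runif(1) * Fe[length(Fe)]
  stats::approx(Fe, tg, xout = u, ties = "ordered")$y
}

# Mean-gap rate such that the dead-time renewal process
# (gap ~ dead + Gamma(mean 1/lambda)) has the requested effective event rate.
calibrate_gap_rate <- function(rate_per_s, dead_s) {
  if (rate_per_s <= 0) return(0)
  mean_interval <- 1 / rate_per_s
  if (mean_interval <= dead_s + 1)
    stop(sprintf(
      "event rate %.3g/s incompatible with refractory dead time %.3g s",
      rate_per_s, dead_s))
  1 / (mean_interval - dead_s)
}

# Between-slice SD of the *latent* baseline rate. The spec's rate_sd_per_min
# is the printed spread of measured per-slice frequencies, which already
# contains the counting noise of one phase window; the latent jitter is what
# remains after subtracting the renewal counting variance.
latent_rate_sd <- function(spec) {
  T_s <- spec$phase_durations_min[["baseline"]] * 60
  rate_s <- spec$baseline_rate_per_min / 60
  dead_s <- spec$duration_mean_s[["baseline"]] + 30
  gap_mean <- 1 / rate_s - dead_s
  if (gap_mean <= 0) return(spec$rate_sd_per_min)
  fano <- (gap_mean / sqrt(GAP_SHAPE) * rate_s)^2   # CV^2 of the interval
  count_var <- fano * rate_s * T_s
  sd_count <- sqrt(count_var) / (T_s / 60)          # per-minute frequency SD
  sqrt(max(0, spec$rate_sd_per_min^2 - sd_count^2))
}

#' Draw per-slice parameters around the group means
#'
#' Slice-to-slice variability: baseline rate, rate ratios, per-phase duration
#' and DC-amplitude means are jittered as truncated normals around the group
#' spec, with field-typical spreads. The latent rate jitter is derived from
#' the printed between-slice frequency SD by subtracting the one-window
#' renewal counting variance, so that the *observed* per-slice frequency
#' spread matches the printed value. A ratio of exactly 0 (full block) is
#' never jittered.
#'
#' @param spec a [group_spec].
#' @return named list of realised slice parameters.
#' @export
draw_slice_params <- function(spec) {
  jr <- function(r) if (r == 0) 0 else rtruncnorm(1, r, spec$ratio_sd, 0.05, 1.6)
  list(
    rate_per_min = rtruncnorm(1, spec$baseline_rate_per_min,
                              latent_rate_sd(spec), 0.06, 0.4),
    ratio_intervention = jr(spec$rate_ratio_intervention),
    ratio_washout = jr(spec$rate_ratio_washout),
    duration_mean_s = rtruncnorm(3, spec$duration_mean_s, 5, 20, 110),
    dc_mean_mV = rtruncnorm(3, spec$dc_mean_mV, 0.15, 0.7, 3.5))
}

#' Generate a synthetic LFP trace with ground-truth SLEs
#'
#' Events follow, per phase, a renewal process: a refractory dead time (event
#' duration + 30 s, so SLEs never overlap) plus a Gamma(shape 4) gap whose
#' mean is calibrated so the *effective* event rate equals the phase rate.
#' The gamma gap reproduces the quasi-periodic recurrence of recorded SLEs;
#' exponential gaps would make counting noise alone exceed the published
#' between-slice frequency spread.
#' Each SLE is a negative DC plateau (sharp onset transient, ~10 s tonic part
#' with continuous ripple-band oscillation, then clonic bursts of ripple and
#' after-discharges) returning to baseline, superimposed on white noise well
#' below the 0.5 mV criterion and optional slow drift.
#'
#' @param spec a [group_spec].
#' @param seed integer seed; fixed seed gives identical samples.
#' @param fs sampling rate in Hz (default 500; Nyquist comfortably above the
#'   default 100-200 Hz ripple band).
#' @param phases character subset of
#'   `c("baseline", "intervention", "washout")` to simulate (consecutively).
#' @param slice optional realised slice parameters from [draw_slice_params];
#'   defaults to the group means.
#' @param noise_sd_mV white background noise SD.
#' @param drift if `TRUE`, add slow (many-minutes period) baseline wander.
#' @param ripple_hz ripple oscillation frequency within each event.
#' @param metadata passed to the trace object.
#' @return list with `trace` (an [lfp_trace]) and `ground_truth` (data.frame:
#'   `onset_s`, `duration_s`, `amplitude_mV`, `phase`, `onset_region`).
#' @export
generate_lfp <- function(spec, seed, fs = 500, phases = PHASES,
                         slice = NULL, noise_sd_mV = 0.05, drift = TRUE,
                         ripple_hz = 140, metadata = list()) {
  validate_group_spec(spec)
  if (fs <= 0) stop("sampling rate must be positive")
  phases <- match.arg(phases, PHASES, several.ok = TRUE)
  durs_min <- spec$phase_durations_min[phases]
  if (any(durs_min <= 0)) stop("phase durations must be positive")
  with_seed(seed, {
    if (is.null(slice))
      slice <- list(rate_per_min = spec$baseline_rate_per_min,
                    ratio_intervention = spec$rate_ratio_intervention,
                    ratio_washout = spec$rate_ratio_washout,
                    duration_mean_s = unname(spec$duration_mean_s),
                    dc_mean_mV = unname(spec$dc_mean_mV))
    ratios <- c(baseline = 1, intervention = slice$ratio_intervention,
                washout = slice$ratio_washout)
    bounds_s <- c(0, cumsum(durs_min * 60))
    n <- as.integer(round(bounds_s[length(bounds_s)] * fs))
    t_total <- n / fs

    x <- stats::rnorm(n, 0, noise_sd_mV)
    if (drift) {
      tt <- seq_len(n) / fs
      ph <- stats::runif(2, 0, 2 * pi)
      x <- x + 0.2 * sin(2 * pi * tt / 1200 + ph[1L]) +
        0.1 * sin(2 * pi * tt / 700 + ph[2L])
    }

    gt <- list()
    base_rate_s <- slice$rate_per_min / 60
    last_end <- -Inf
    for (j in seq_along(phases)) {
      pj <- phases[j]
      idx <- match(pj, PHASES)
      # drug phases scale the slice's *realized* baseline rate: the effect is
      # proportional to the slice's own manifest activity, and the mean of
      # per-slice count ratios then estimates the ratio without small-count
      # (Jensen) bias
      rate_s <- base_rate_s * ratios[pj]
      if (rate_s <= 0) next
      dmean <- slice$duration_mean_s[idx]
      lam <- calibrate_gap_rate(rate_s, dmean + 30)
      # 15 s lead-in gives every event a clean pre-onset baseline window; the
      # refractory gap after a straddling event from the previous phase is
      # honoured so events never overlap
      start_t <- bounds_s[j] + 15
      t_cur <- if (last_end + 30 > start_t)
        last_end + 30 + draw_gap(1, lam)
      else
        start_t + eq_first_delay(lam, dmean + 30)
      while (t_cur < bounds_s[j + 1L]) {
        # events may straddle the phase boundary; they belong to the phase
        # containing their onset (waveforms are clipped at the trace end)
        dur <- rtruncnorm(1, dmean, spec$duration_sd_s[idx], 15, 120)
        amp <- rtruncnorm(1, slice$dc_mean_mV[idx], spec$dc_sd_mV[idx],
                          0.6, 4)
        region <- sample(REGIONS, 1L, prob = spec$onset_region_weights)
        gt[[length(gt) + 1L]] <- data.frame(
          onset_s = t_cur, duration_s = dur, amplitude_mV = amp,
          phase = pj, onset_region = region)
        x <- add_sle_waveform(x, fs, t_cur, dur, amp, ripple_hz)
        last_end <- t_cur + dur
        t_cur <- last_end + 30 + draw_gap(1, lam)
      }
      if (pj == "baseline") {
        n_base <- sum(vapply(gt, function(g) g$phase == "baseline", logical(1)))
        if (n_base > 0L)
          base_rate_s <- n_base / (bounds_s[j + 1L] - bounds_s[j])
      }
    }
    gt <- if (length(gt)) do.call(rbind, gt) else
      data.frame(onset_s = numeric(0), duration_s = numeric(0),
                 amplitude_mV = numeric(0), phase = character(0),
                 onset_region = character(0))

    ph_df <- data.frame(phase = phases,
                        start_s = bounds_s[-length(bounds_s)],
                        end_s = bounds_s[-1L])
    list(trace = lfp_trace(x, fs, ph_df,
                           c(metadata, list(group = spec$group_label,
                                            seed = seed))),
         ground_truth = gt)
  })
}

# Superimpose one SLE on sample vector x (in place, returned).
add_sle_waveform <- function(x, fs, onset_s, dur_s, amp_mV, ripple_hz) {
  fall_s <- 2; rise_s <- 0.5
  i0 <- as.integer(round(onset_s * fs)) + 1L
  i1 <- min(length(x), as.integer(round((onset_s + dur_s + fall_s) * fs)))
  t <- (seq.int(i0, i1) - i0) / fs  # time from onset
  env <- pmin(pmin(t / rise_s, 1), pmax(0, 1 - (t - dur_s) / fall_s))
  v <- -amp_mV * env
  # sharp onset transient
  v <- v - 0.4 * exp(-t / 0.15) * (t < 1)
  # tonic part: continuous ripple riding the plateau
  tonic <- t >= rise_s & t < min(10, dur_s)
  rip <- 0.12 * sin(2 * pi * ripple_hz * t)
  v <- v + rip * tonic
  # clonic part: rhythmic bursts of ripple plus small after-discharges
  clonic <- t >= 10 & t <= dur_s
  if (any(clonic)) {
    gate <- sin(pi * 1.5 * (t - 10))^2
    gate <- gate^3 * clonic
    # ripple bursts with a small after-discharge deflection; the DC component
    # stays small so the reported peak amplitude tracks the plateau
    v <- v + (rip - 0.08) * gate
  }
  x[seq.int(i0, i1)] <- x[seq.int(i0, i1)] + v
  x
}

#' Generate a cohort of slice experiments
#'
#' Per-slice seeds are derived deterministically from the master seed; each
#' slice's parameters are jittered around the group means via
#' [draw_slice_params].
#'
#' @inheritParams generate_lfp
#' @param n_slices number of slices (>= 1).
#' @param seed master seed; fixed seed reproduces the cohort exactly.
#' @return list of slice experiments, each with `slice_id`, `animal_id`,
#'   `params`, `trace`, `ground_truth`.
#' @export
generate_cohort <- function(spec, n_slices = spec$n_slices, seed, fs = 500,
                            phases = PHASES, drift = TRUE) {
  validate_group_spec(spec)
  if (n_slices < 1L) stop("n_slices must be >= 1")
  seeds <- derive_seeds(seed, 2L * n_slices)
  lapply(seq_len(n_slices), function(i) {
    params <- with_seed(seeds[2L * i - 1L], draw_slice_params(spec))
    sim <- generate_lfp(spec, seed = seeds[2L * i], fs = fs, phases = phases,
                        slice = params, drift = drift,
                        metadata = list(slice_id = sprintf("%s_s%02d",
                                                           spec$group_label, i),
                                        animal_id = sprintf("%s_a%02d",
                                                            spec$group_label, i),
                                        viable = TRUE))
    list(slice_id = sprintf("%s_s%02d", spec$group_label, i),
         animal_id = sprintf("%s_a%02d", spec$group_label, i),
         params = params, trace = sim$trace, ground_truth = sim$ground_truth)
  })
}
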