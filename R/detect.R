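# Electrographic SLE detection: 0.5 mV negative DC shift, >= 10 s, ripple.

#' Detection settings
#'
#' Thresholds default to the model's electrographic criteria: a negative
#' field-potential deflection of at least 0.5 mV from the local pre-event
#' baseline, sustained for at least 10 s, with superimposed ripple-like
#' discharges (operationalised as ripple-band power at least
#' `ripple_factor` times the pre-event baseline, sustained >= 1 s).
#'
#' @param dc_threshold_mV minimum DC deflection magnitude (default 0.5).
#' @param min_duration_s minimum event duration (default 10).
#' @param ripple_band numeric length-2, ripple band in Hz (default 100-200).
#' @param ripple_factor required ripple-power ratio vs pre-event baseline.
#' @param baseline_window_s window preceding a candidate onset whose median
#'   defines the local baseline (default 10).
#' @param envelope_rate_hz sampling rate of the decimated DC envelope used
#'   for threshold logic (default 10).
#' @return list of class `detection_params`.
#' @export
detection_params <- function(dc_threshold_mV = 0.5, min_duration_s = 10,
                             ripple_band = c(100, 200), ripple_factor = 3,
                             baseline_window_s = 10, envelope_rate_hz = 10) {
  stopifnot(dc_threshold_mV > 0, min_duration_s > 0, ripple_factor > 0,
            baseline_window_s > 0, envelope_rate_hz > 0,
            length(ripple_band) == 2L, ripple_band[1L] < ripple_band[2L])
  structure(list(dc_threshold_mV = dc_threshold_mV,
                 min_duration_s = min_duration_s,
                 ripple_band = ripple_band, ripple_factor = ripple_factor,
                 baseline_window_s = baseline_window_s,
                 envelope_rate_hz = envelope_rate_hz),
            class = "detection_params")
}

#' Remove slow baseline drift
#'
#' Estimates the slow baseline on a 1 Hz decimated copy and subtracts it,
#' attenuating many-minutes-scale wander while leaving DC shifts of tens of
#' seconds intact. Because SLEs are negative-going and can locally occupy
#' more than half of any median window (dense event clusters), the estimate
#' is made event-blind first: samples falling clearly below the local upper
#' envelope (running max over +/- 90 s; with a >= 30 s inter-event gap that
#' envelope always touches clean baseline) are replaced by interpolation
#' between clean neighbours, and the running median at the `1 / cutoff_hz`
#' time scale is taken on the cleaned signal.
#'
#' @param trace an [lfp_trace].
#' @param cutoff_hz corner frequency of the drift to remove; must be well
#'   below the DC-shift band (default 1/600 Hz, a 10-minute window) and
#'   below Nyquist.
#' @return drift-corrected [lfp_trace] of identical length.
#' @export
remove_drift <- function(trace, cutoff_hz = 1 / 600) {
  stopifnot(inherits(trace, "lfp_trace"))
  if (cutoff_hz >= trace$fs / 2) stop("cutoff at or above Nyquist")
  if (cutoff_hz <= 0) stop("cutoff must be positive")
  x <- trace$samples
  n <- length(x)
  window_s <- 1 / cutoff_hz
  dec <- max(1L, as.integer(trace$fs))  # 1 Hz working copy
  e <- block_mean(x, dec)
  if (length(e) < 5L) {
    base <- rep(stats::median(x), n)
  } else {
    # event-blind cleaning: anything 0.3 mV below the local upper envelope
    # is ictal content, not baseline
    ref <- running_max(e, 90L)
    bad <- e < ref - 0.3
    # a mask covering most of the trace means steep monotone drift fooled
    # the envelope (ramp max is offset by slope x window), not dense events;
    # the plain median handles ramps fine
    if (mean(bad) > 0.6) bad[] <- FALSE
    if (any(bad) && sum(!bad) >= 2L) {
      idx <- seq_along(e)
      e[bad] <- stats::approx(idx[!bad], e[!bad], xout = idx[bad],
                              rule = 2L)$y
    }
    k <- as.integer(window_s)
    k <- min(k + (1L - k %% 2L), length(e) - (1L - length(e) %% 2L))
    if (k < 3L) k <- 3L
    # endrule "constant": shrinking end-windows would let an event near a
    # trace edge dominate its own baseline and be flattened away
    be <- stats::runmed(e, k, endrule = "constant")
    t_e <- (seq_along(e) - 0.5) * dec / trace$fs
    base <- stats::approx(t_e, be, xout = seq_len(n) / trace$fs,
                          rule = 2L)$y
  }
  trace$samples <- x - base
  trace
}

#' Detect seizure-like events
#'
#' Finds the maximal intervals satisfying all three electrographic criteria:
#'
#' 1. the low-pass DC envelope deflects negatively by at least
#'    `dc_threshold_mV` from the local baseline (median of the
#'    `baseline_window_s` seconds preceding the candidate onset);
#' 2. the deflection persists for at least `min_duration_s` (onset and offset
#'    placed at the first/last crossing of 50% of the peak deflection);
#' 3. ripple-band power within the interval exceeds the pre-event baseline
#'    power by `ripple_factor`, sustained for at least 1 s.
#'
#' The amplitude reported is the magnitude of the peak envelope deflection
#' from the frozen pre-onset baseline. Events are sorted by onset and
#' assigned the protocol phase containing their onset (`NA` if the trace has
#' no phase annotation).
#'
#' @param trace a drift-corrected [lfp_trace].
#' @param params a [detection_params] object.
#' @return data.frame of class `sle_events`: `onset_s`, `offset_s`,
#'   `duration_s`, `dc_shift_mV`, `ripple_confirmed`, `phase`.
#' @export
detect_sles <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "lfp_trace"))
  x <- trace$samples
  if (any(!is.finite(x))) stop("trace contains non-finite samples")
  fs <- trace$fs
  p <- params
  if (p$ripple_band[1L] >= fs / 2)
    stop("ripple band lies above Nyquist for this sampling rate")

  dec <- max(1L, as.integer(round(fs / p$envelope_rate_hz)))
  e <- block_mean(x, dec)
  er <- fs / dec                      # actual envelope rate
  # extra smoothing at the 1 s scale: ripple/burst content averages out
  ksm <- max(1L, as.integer(round(er)))
  if (ksm > 1L)
    e <- stats::filter(e, rep(1 / ksm, ksm), sides = 2L) |>
      (\(v) { v[is.na(v)] <- e[is.na(v)]; as.numeric(v) })()
  nb <- as.integer(round(p$baseline_window_s * er))
  b <- rolling_baseline(e, nb)
  dthr <- p$dc_threshold_mV
  below <- which(e - b <= -dthr)
  events <- list()
  used_until <- 0L
  for (i in below) {
    if (i <= used_until) next
    B <- b[i]
    # expand the candidate at half-threshold hysteresis around the trigger
    j0 <- i; while (j0 > 1L && e[j0 - 1L] - B <= -dthr / 2) j0 <- j0 - 1L
    j1 <- i; while (j1 < length(e) && e[j1 + 1L] - B <= -dthr / 2) j1 <- j1 + 1L
    peak <- min(e[j0:j1]) - B        # negative
    half <- B + 0.5 * peak
    k0 <- j0 + which(e[j0:j1] <= half)[1L] - 1L
    k1 <- j0 + max(which(e[j0:j1] <= half)) - 1L
    used_until <- j1
    onset_s <- (k0 - 0.5) * dec / fs
    offset_s <- (k1 + 0.5) * dec / fs
    dur <- offset_s - onset_s
    if (abs(peak) < dthr || dur < p$min_duration_s) next
    events[[length(events) + 1L]] <-
      data.frame(onset_s = onset_s, offset_s = offset_s, duration_s = dur,
                 dc_shift_mV = abs(peak))
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(onset_s = numeric(0), offset_s = numeric(0),
               duration_s = numeric(0), dc_shift_mV = numeric(0))

  # criterion 3: sustained ripple-band power elevation
  ev$ripple_confirmed <- vapply(seq_len(nrow(ev)), function(k) {
    ripple_elevated(x, fs, ev$onset_s[k], ev$offset_s[k],
                    p$ripple_band, p$ripple_factor, p$baseline_window_s)
  }, logical(1))
  ev <- ev[ev$ripple_confirmed, , drop = FALSE]
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  rownames(ev) <- NULL

  ev$phase <- rep(NA_character_, nrow(ev))
  if (!is.null(trace$phases) && nrow(ev) > 0L) {
    for (r in seq_len(nrow(trace$phases)))
      ev$phase[ev$onset_s >= trace$phases$start_s[r] &
                 ev$onset_s < trace$phases$end_s[r]] <- trace$phases$phase[r]
  }
  class(ev) <- c("sle_events", "data.frame")
  ev
}

# TRUE iff ripple-band power within [onset, offset] exceeds `factor` times the
# pre-onset baseline band power, sustained over >= 1 s (two 0.5 s windows).
ripple_elevated <- function(x, fs, onset_s, offset_s, band, factor,
                            baseline_window_s) {
  i0 <- max(1L, as.integer((onset_s - baseline_window_s) * fs))
  i1 <- min(length(x), as.integer(offset_s * fs))
  seg <- x[i0:i1]
  bp <- fft_bandpass(seg, fs, band)
  wlen <- max(2L, as.integer(round(0.5 * fs)))
  nw <- length(bp) %/% wlen
  if (nw < 3L) return(FALSE)
  pw <- .colMeans(bp[seq_len(nw * wlen)]^2, wlen, nw)
  n_pre <- max(1L, as.integer((onset_s * fs - i0) / wlen))
  base_p <- stats::median(pw[seq_len(n_pre)])
  if (base_p <= 0) base_p <- .Machine$double.eps
  hot <- pw[-seq_len(n_pre)] >= factor * base_p
  any(hot[-length(hot)] & hot[-1L])   # two consecutive windows
}

#' Slice inclusion rule
#'
#' A slice is included iff at least one SLE onset occurs within 45 min of the
#' start of 4-AP perfusion.
#'
#' @param events an `sle_events` data.frame.
#' @param fourAP_start_s perfusion start time, seconds (default 0).
#' @param limit_min inclusion window, minutes (default 45).
#' @return logical flag.
#' @export
check_slice_inclusion <- function(events, fourAP_start_s = 0,
                                  limit_min = 45) {
  nrow(events) > 0L &&
    any(events$onset_s >= fourAP_start_s &
          events$onset_s <= fourAP_start_s + limit_min * 60)
}

#' Summarise SLEs within one protocol phase
#'
#' Frequency is the count of all in-phase events divided by the full phase
#' duration (per minute) — a full block therefore has a well-defined
#' frequency of 0. Duration and DC-shift means are computed over the *last*
#' `k` in-phase events (3-5, to ensure effects have reached a plateau), or
#' all events if fewer exist; with zero events they are `NA`.
#'
#' @param events an `sle_events` data.frame (from [detect_sles]).
#' @param phase_window list or one-row data.frame with `phase`, `start_s`,
#'   `end_s`.
#' @param k number of end-of-phase events to average (3-5, default 5).
#' @return one-row data.frame of class `phase_summary`: `phase`,
#'   `sle_frequency_per_min`, `mean_duration_s`, `mean_dc_shift_mV`,
#'   `n_events_total`, `n_events_analyzed`.
#' @export
summarize_phase <- function(events, phase_window, k = 5L) {
  if (k < 3L || k > 5L) stop("k must be between 3 and 5")
  w <- as.list(phase_window)
  if (w$end_s <= w$start_s) stop("invalid phase window")
  inph <- events[events$onset_s >= w$start_s & events$onset_s < w$end_s, ,
                 drop = FALSE]
  n <- nrow(inph)
  dur_min <- (w$end_s - w$start_s) / 60
  last_k <- if (n > 0L) inph[seq.int(max(1L, n - k + 1L), n), , drop = FALSE]
  else inph
  out <- data.frame(
    phase = w$phase %||% NA_character_,
    sle_frequency_per_min = n / dur_min,
    mean_duration_s = if (n > 0L) mean(last_k$duration_s) else NA_real_,
    mean_dc_shift_mV = if (n > 0L) mean(last_k$dc_shift_mV) else NA_real_,
    n_events_total = n,
    n_events_analyzed = nrow(last_k))
  class(out) <- c("phase_summary", "data.frame")
  out
}

#' Summarise all annotated phases of a trace
#'
#' Convenience wrapper: [detect_sles] output plus per-phase
#' [summarize_phase] rows for every phase window annotated on the trace.
#'
#' @param trace an [lfp_trace] with phase annotations.
#' @param events optional precomputed `sle_events`.
#' @param params detection settings used if `events` is missing.
#' @param k passed to [summarize_phase].
#' @return data.frame with one row per phase.
#' @export
summarize_trace <- function(trace, events = NULL,
                            params = detection_params(), k = 5L) {
  if (is.null(trace$phases)) stop("trace has no phase annotation")
  if (is.null(events)) events <- detect_sles(remove_drift(trace), params)
  do.call(rbind, lapply(seq_len(nrow(trace$phases)), function(i)
    summarize_phase(events, trace$phases[i, ], k = k)))
}
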