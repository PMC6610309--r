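# Shared fixtures built in code (no stored data files).

# short noise trace with SLEs stamped at known positions; bypasses the
# group-spec phase-duration constraint so oracle tests can stay tiny
make_test_trace <- function(onsets_s, durations_s, amps_mV, total_s = 300,
                            fs = 500, noise_sd = 0.05, seed = 1,
                            phases = NULL) {
  apseize:::with_seed(seed, {
    x <- stats::rnorm(total_s * fs, 0, noise_sd)
    for (i in seq_along(onsets_s))
      x <- apseize:::add_sle_waveform(x, fs, onsets_s[i], durations_s[i],
                                      amps_mV[i], ripple_hz = 140)
    lfp_trace(x, fs, phases = phases)
  })
}

# brute-force SLE finder: independent straight-loop evaluation of the three
# criteria on a 2 Hz decimated copy; reference for detector equivalence
oracle_detect <- function(trace, dc_thr = 0.5, min_dur = 10) {
  fs <- trace$fs
  dec <- as.integer(fs / 2)           # 2 Hz grid
  x <- trace$samples
  n2 <- length(x) %/% dec
  e <- vapply(seq_len(n2), function(i)
    mean(x[((i - 1L) * dec + 1L):(i * dec)]), numeric(1))
  # causal baseline: plain-loop median of the preceding 10 s
  b <- numeric(n2)
  for (i in seq_len(n2)) {
    lo <- max(1L, i - 20L)
    b[i] <- stats::median(e[lo:max(lo, i - 1L)])
  }
  below <- e - b <= -dc_thr
  events <- list()
  i <- 1L
  while (i <= n2) {
    if (!below[i]) { i <- i + 1L; next }
    B <- b[i]
    j <- i
    while (j < n2 && e[j + 1L] - B <= -dc_thr / 2) j <- j + 1L
    peak <- min(e[i:j]) - B
    half <- which(e[i:j] <= B + peak / 2)
    on_s <- (i + half[1L] - 1.5) / 2
    off_s <- (i + half[length(half)] - 0.5) / 2
    dur <- off_s - on_s
    if (abs(peak) >= dc_thr && dur >= min_dur) {
      # independent ripple check: periodogram band power ratio
      seg <- x[max(1, on_s * fs):min(length(x), off_s * fs)]
      pre <- x[max(1, (on_s - 10) * fs):max(2, on_s * fs)]
      bandpow <- function(v) {
        sp <- stats::spec.pgram(stats::ts(v, frequency = fs), plot = FALSE,
                                taper = 0)
        mean(sp$spec[sp$freq >= 100 & sp$freq <= 200])
      }
      if (bandpow(seg) >= 3 * bandpow(pre))
        events[[length(events) + 1L]] <-
          c(onset = on_s, offset = off_s, peak = abs(peak))
    }
    i <- j + 1L
  }
  if (length(events)) as.data.frame(do.call(rbind, events)) else
    data.frame(onset = numeric(0), offset = numeric(0), peak = numeric(0))
}

# tiny dtt_stack built directly from an intensity array (control level 100)
make_dtt_stack <- function(frames, n_control = 5L, masks = NULL) {
  ser <- ios_series(frames,
                    frame_times_s = seq_len(dim(frames)[3L]) - n_control - 1L,
                    n_control_frames = n_control, masks = masks)
  compute_dtt(ser)
}

# mask set wrapper for arbitrary small test masks
as_mask_set <- function(masks) {
  structure(masks, class = "region_mask_set",
            frame_dim = c(height = nrow(masks[[1L]]),
                          width = ncol(masks[[1L]])))
}

expect_close <- function(actual, expected, rel = NULL, abs = NULL) {
  if (!is.null(rel))
    expect_lt(abs(actual - expected), rel * abs(expected))
  if (!is.null(abs))
    expect_lt(abs(actual - expected), abs)
}
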