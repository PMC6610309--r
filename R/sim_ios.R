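# Synthetic trigger-aligned IOS image stacks with known involvement ground truth.

#' Construct an IOS series object
#'
#' @param frames integer array `height x width x n_frames`, 8-bit intensities.
#' @param frame_times_s numeric, strictly increasing times relative to the
#'   electrical SLE onset (negative = pre-onset).
#' @param n_control_frames number of initial frames used as the control image.
#' @param masks a [region_masks] set matching the frame size.
#' @param event optional linked SLE description (list or data.frame row).
#' @param ground_truth optional list of per-region involved pixel indices.
#' @return object of class `ios_series`.
#' @export
ios_series <- function(frames, frame_times_s, n_control_frames = 20L,
                       masks = NULL, event = NULL, ground_truth = NULL) {
  stopifnot(length(dim(frames)) == 3L)
  n <- dim(frames)[3L]
  if (length(frame_times_s) != n) stop("frame_times_s length mismatch")
  if (any(diff(frame_times_s) <= 0)) stop("frame times must strictly increase")
  if (n < n_control_frames)
    stop("stack shorter than the control window")
  if (frame_times_s[n_control_frames] >= 0)
    stop("all control frames must precede the electrical onset")
  if (!is.null(masks)) {
    d <- attr(masks, "frame_dim")
    stopifnot(d["height"] == dim(frames)[1L], d["width"] == dim(frames)[2L])
  }
  structure(list(frames = frames, frame_times_s = frame_times_s,
                 n_control_frames = as.integer(n_control_frames),
                 masks = masks, event = event, ground_truth = ground_truth),
            class = "ios_series")
}

#' @export
print.ios_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<ios_series> %d frames of %d x %d (%d control)\n",
              d[3L], d[2L], d[1L], x$n_control_frames))
  invisible(x)
}

# unit trapezoidal pixel transient sampled on the frame grid:
# 2-frame rise, `plateau` frames at 1, 2-frame fall
unit_transient <- function(plateau = 16L, ramp = 2L) {
  c(seq_len(ramp) / ramp, rep(1, plateau), rev(seq_len(ramp) / ramp) - 1 / ramp)
}

# triangular-density activation offsets (frames) over a spread window W,
# decorrelated from the spatial pixel order by a golden-ratio permutation
activation_offsets <- function(k, W) {
  u <- (seq_len(k) - 0.5) / k
  q <- ifelse(u < 0.5, W * sqrt(u / 2), W * (1 - sqrt((1 - u) / 2)))
  o <- as.integer(round(q))
  o[order((seq_len(k) * 0.6180339887) %% 1)]
}

# evenly strided subset of the mask pixels: exact count, spatially uniform
stride_select <- function(mask_idx, k) {
  m <- length(mask_idx)
  if (k <= 0L) return(integer(0))
  if (k >= m) return(mask_idx)
  mask_idx[floor((seq_len(k) - 0.5) * m / k) + 1L]
}

#' Generate a synthetic IOS image stack for one SLE
#'
#' Produces a trigger-aligned 8-bit frame stack: `n_control_frames` pre-onset
#' control frames, then a propagating transmittance transient. In each region
#' an exact fraction of mask pixels (the spec's area fraction) becomes
#' *involved*: each involved pixel runs through an above-threshold trapezoidal
#' dT/T transient (>= `a_min` percent, held long enough to satisfy the
#' 1 percent / 10-consecutive-frame rule by construction), with activation
#' times staggered across a spread window to emulate continuous propagation;
#' the designated onset region rises first. The per-pixel amplitude is
#' calibrated deterministically so the *noiseless* 20 x 20 ROI mean time
#' course at the region centroid peaks exactly at the spec's regional dT/T
#' (ROI intensity mixes involved and uninvolved pixels, which is how a sub-1%
#' ROI dT/T coexists with a large involved area). Frame noise plus stochastic
#' rounding to 8 bits keeps per-ROI dT/T fluctuations below 0.1% and the
#' quantisation unbiased.
#'
#' @param event list or data.frame row with at least `onset_region` and
#'   `duration_s` (and optionally `phase`).
#' @param masks a [region_masks] set.
#' @param spec a [group_spec]; regional amplitudes/areas are taken from its
#'   `ios_peak_dtt_pct` / `area_fraction_pct` for `phase`.
#' @param seed integer seed (noise and jitter only; the activation design is
#'   deterministic).
#' @param phase protocol phase to read the regional parameters from; default
#'   the event's phase.
#' @param frame_rate frames per second (default 2).
#' @param n_control_frames control frames preceding the onset (default 20).
#' @param baseline_intensity mean 8-bit transmittance of the unperturbed
#'   slice image.
#' @param noise_sd frame noise SD in intensity counts.
#' @param jitter if `TRUE` (default), regional area (SD 4 percentage points)
#'   and amplitude (SD 7% relative) are jittered per stack around the spec
#'   means, emulating SLE-to-SLE variability.
#' @param a_min,a_max admissible per-pixel plateau dT/T (%); the spread
#'   window grows until the calibrated amplitude is >= `a_min`.
#' @return an [ios_series]; its `ground_truth` holds the per-region involved
#'   pixel indices and realised parameters.
#' @export
generate_ios_series <- function(event, masks, spec, seed,
                                phase = NULL, frame_rate = 2,
                                n_control_frames = 20L,
                                baseline_intensity = 180,
                                noise_sd = 0.3, jitter = TRUE,
                                a_min = 2, a_max = 8) {
  validate_group_spec(spec)
  if (frame_rate <= 0) stop("frame_rate must be positive")
  phase <- phase %||% event$phase %||% "baseline"
  phase <- match.arg(phase, PHASES)
  dims <- attr(masks, "frame_dim")
  h <- dims[["height"]]; w <- dims[["width"]]; n_px <- h * w
  plateau <- 16L; ramp <- 2L
  u <- unit_transient(plateau, ramp)
  support <- length(u)

  with_seed(seed, {
    design <- list()
    max_end <- 0L
    lat_step <- 3L
    lat_next <- lat_step
    onset_first <- c(event$onset_region,
                     setdiff(REGIONS, event$onset_region))
    for (r in onset_first) {
      f_pct <- spec$area_fraction_pct[r, phase]
      dtt <- spec$ios_peak_dtt_pct[r, phase]
      if (is.na(f_pct) || is.na(dtt) || f_pct <= 0 || dtt <= 0) next
      if (jitter) {
        f_pct <- rtruncnorm(1, f_pct, 4, 0, 100)
        dtt <- rtruncnorm(1, dtt, 0.07 * dtt, 0.05, 10)
      }
      lat <- if (r == event$onset_region) 0L else { v <- lat_next
        lat_next <- lat_next + lat_step; v }
      mask_idx <- which(masks[[r]])
      k <- as.integer(round(f_pct / 100 * length(mask_idx)))
      if (k == 0L) next
      sel <- stride_select(mask_idx, k)
      roi <- roi_rect(masks[[r]], 20L)
      roi_idx <- as.vector(outer(roi$rows, (roi$cols - 1L) * h, `+`))

      W <- max(10L, as.integer(round(0.4 * (event$duration_s %||% 55) *
                                       frame_rate)))
      repeat {
        off <- activation_offsets(k, W)
        in_roi <- sel %in% roi_idx
        if (!any(in_roi)) { a <- min(a_max, max(a_min, dtt / (f_pct / 100)))
          break }
        cnt <- tabulate(off[in_roi] + 1L, nbins = W + 1L)
        m_unit <- stats::filter(c(cnt, numeric(support)), rev(u),
                                method = "convolution", sides = 1L)
        peak_unit <- max(m_unit, na.rm = TRUE) / length(roi_idx)
        a <- dtt / peak_unit
        if (a >= a_min || W >= 250L) break
        W <- min(250L, as.integer(ceiling(W * 1.5)))
      }
      a <- min(a, a_max)
      design[[r]] <- list(region = r, idx = sel, offsets = off, lat = lat,
                          amplitude_pct = a, area_pct = f_pct,
                          target_dtt_pct = dtt, spread_frames = W)
      max_end <- max(max_end, lat + W + support)
    }

    onset_frame <- n_control_frames + 3L  # first post-trigger activity frame
    n_frames <- onset_frame + max(max_end + 8L, 30L)
    if (n_frames < n_control_frames + 10L + 2L)
      stop("stack shorter than control window plus persistence requirement")

    sig <- matrix(0, n_px, n_frames)  # designed dT/T in %
    for (d in design) {
      starts <- onset_frame + d$lat + d$offsets
      for (o in sort(unique(d$offsets))) {
        px <- d$idx[d$offsets == o]
        t0 <- onset_frame + d$lat + o
        cols <- t0 + seq_len(support) - 1L
        sig[px, cols] <- sig[px, cols] +
          matrix(d$amplitude_pct * u, length(px), support, byrow = TRUE)
      }
    }

    inten <- baseline_intensity * (1 + sig / 100) +
      stats::rnorm(length(sig), 0, noise_sd)
    # stochastic rounding: unbiased 8-bit quantisation
    fl <- floor(inten)
    inten <- fl + (stats::runif(length(inten)) < (inten - fl))
    inten <- pmin(pmax(inten, 0), 255)

    gt <- lapply(design, function(d)
      list(involved_idx = d$idx, amplitude_pct = d$amplitude_pct,
           area_pct = d$area_pct, target_dtt_pct = d$target_dtt_pct,
           latency_frames = d$lat, spread_frames = d$spread_frames))

    ios_series(array(as.integer(inten), dim = c(h, w, n_frames)),
               frame_times_s = (seq_len(n_frames) - onset_frame) / frame_rate,
               n_control_frames = n_control_frames,
               masks = masks, event = event, ground_truth = gt)
  })
}
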