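# dT/T computation, ROI summaries, threshold-persistence involvement, areas.

#' Compute the dT/T stack from an IOS series
#'
#' The control image is the per-pixel mean of the first `n_control_frames`
#' frames (recorded before the ictal onset); each frame is then expressed as
#' percent change relative to it:
#' `dTT[f, p] = 100 * (I[f, p] - C[p]) / C[p]`.
#' Pixels with zero control intensity are flagged invalid (`NA` throughout);
#' frames at the 8-bit ceiling (255) are saturated and excluded (`NA`).
#'
#' @param series an [ios_series].
#' @return object of class `dtt_stack`: list with `dtt` (array
#'   `height x width x n_frames`, percent), `control` (matrix), `invalid`
#'   (logical matrix), plus frame times, control count and masks carried over.
#' @export
compute_dtt <- function(series) {
  stopifnot(inherits(series, "ios_series"))
  fr <- series$frames
  h <- dim(fr)[1L]; w <- dim(fr)[2L]; n <- dim(fr)[3L]
  nc <- series$n_control_frames
  if (n < nc) stop("stack shorter than the control window")
  m <- fr
  dim(m) <- c(h * w, n)
  ctrl <- rowMeans(m[, seq_len(nc), drop = FALSE])
  invalid <- ctrl <= 0
  sat <- m >= 255L
  d <- 100 * (m - ctrl) / ifelse(invalid, NA_real_, ctrl)
  d[sat] <- NA_real_
  dim(d) <- c(h, w, n)
  structure(list(dtt = d, control = matrix(ctrl, h, w),
                 invalid = matrix(invalid, h, w),
                 frame_times_s = series$frame_times_s,
                 n_control_frames = nc, masks = series$masks),
            class = "dtt_stack")
}

#' Place a square ROI at a region mask's centroid
#'
#' The ROI is snapped to lie inside the mask: starting from the centroid, a
#' local grid of shifts is searched for a fully inside window; if none exists
#' the ROI is shrunk (with a warning) to the largest inside square.
#'
#' @param mask logical matrix.
#' @param size ROI edge length in pixels (default 20).
#' @return list with integer vectors `rows` and `cols`.
#' @export
roi_rect <- function(mask, size = 20L) {
  size <- as.integer(size)
  ij <- which(mask, arr.ind = TRUE)
  if (nrow(ij) == 0L) stop("empty mask")
  h <- nrow(mask); w <- ncol(mask)
  place <- function(sz) {
    cy <- as.integer(round(mean(ij[, 1L]))); cx <- as.integer(round(mean(ij[, 2L])))
    half <- sz %/% 2L
    best <- NULL; best_cov <- -1L
    for (dy in seq(-16L, 16L, by = 2L)) for (dx in seq(-16L, 16L, by = 2L)) {
      r0 <- min(max(cy + dy - half, 1L), h - sz + 1L)
      c0 <- min(max(cx + dx - half, 1L), w - sz + 1L)
      cov <- sum(mask[r0:(r0 + sz - 1L), c0:(c0 + sz - 1L)])
      if (cov > best_cov) { best_cov <- cov; best <- c(r0, c0) }
      if (cov == sz * sz) return(list(rows = r0:(r0 + sz - 1L),
                                      cols = c0:(c0 + sz - 1L), full = TRUE))
    }
    list(rows = best[1L]:(best[1L] + sz - 1L),
         cols = best[2L]:(best[2L] + sz - 1L), full = best_cov == sz * sz)
  }
  sz <- min(size, h, w)
  res <- place(sz)
  while (!res$full && sz > 4L) { sz <- sz - 4L; res <- place(sz) }
  if (sz < size)
    warning(sprintf("region mask too small for a %d px ROI; shrunk to %d px",
                    size, sz))
  res[c("rows", "cols")]
}

#' Per-region ROI dT/T time courses and peak summaries
#'
#' A `roi_size` x `roi_size` ROI is placed at each region's mask centroid
#' ([roi_rect]); the region's time course is the mean dT/T over ROI pixels per
#' frame (invalid/saturated pixels excluded) and the summary is the peak of
#' that time course after the control window (i.e., during the SLE).
#'
#' @param dtt a `dtt_stack` from [compute_dtt].
#' @param masks a [region_masks] set (defaults to the one carried in `dtt`).
#' @param roi_size ROI edge in pixels (default 20).
#' @return list with `time_course` (region x frame matrix, percent) and
#'   `peak_pct` (named vector).
#' @export
roi_intensity <- function(dtt, masks = dtt$masks, roi_size = 20L) {
  stopifnot(inherits(dtt, "dtt_stack"), !is.null(masks))
  d <- dtt$dtt
  h <- dim(d)[1L]; n <- dim(d)[3L]
  dim(d) <- c(h * dim(dtt$dtt)[2L], n)
  post <- seq.int(dtt$n_control_frames + 1L, n)
  tc <- matrix(NA_real_, length(masks), n,
               dimnames = list(names(masks), NULL))
  for (r in names(masks)) {
    roi <- roi_rect(masks[[r]], roi_size)
    idx <- as.vector(outer(roi$rows, (roi$cols - 1L) * h, `+`))
    tc[r, ] <- colMeans(d[idx, , drop = FALSE], na.rm = TRUE)
  }
  list(time_course = tc,
       peak_pct = apply(tc[, post, drop = FALSE], 1L, max, na.rm = TRUE))
}

#' Threshold-persistence involvement map
#'
#' A pixel is *involved* in the SLE iff its dT/T reaches `threshold_pct` in at
#' least `persistence_frames` consecutive frames anywhere in the captured
#' series (pure per-pixel thresholding, no spatial smoothing). The default
#' 1% / 10 frames implements the "at least 1% in more than 9 subsequent
#' images" rule.
#'
#' @param dtt a `dtt_stack`.
#' @param threshold_pct dT/T threshold in percent (default 1).
#' @param persistence_frames required consecutive frames at/above threshold
#'   (default 10).
#' @return logical `height x width` matrix.
#' @export
involvement_map <- function(dtt, threshold_pct = 1, persistence_frames = 10L) {
  stopifnot(inherits(dtt, "dtt_stack"))
  persistence_frames <- as.integer(persistence_frames)
  if (persistence_frames < 1L) stop("persistence_frames must be >= 1")
  d <- dtt$dtt
  h <- dim(d)[1L]; w <- dim(d)[2L]; n <- dim(d)[3L]
  if (persistence_frames > n) {
    warning("persistence exceeds stack length; no pixel can be involved")
    return(matrix(FALSE, h, w))
  }
  dim(d) <- c(h * w, n)
  above <- !is.na(d) & d >= threshold_pct
  run <- integer(h * w)
  inv <- logical(h * w)
  for (f in seq_len(n)) {
    run <- ifelse(above[, f], run + 1L, 0L)
    inv <- inv | run >= persistence_frames
  }
  matrix(inv, h, w)
}

#' Per-region SLE area
#'
#' Percent of each anatomical region's mask pixels that are involved:
#' `100 * |involved AND mask_r| / |mask_r|`.
#'
#' @param involvement logical matrix from [involvement_map].
#' @param masks a [region_masks] set.
#' @return named numeric vector of area percentages.
#' @export
sle_area <- function(involvement, masks) {
  vapply(masks, function(m) 100 * sum(involvement & m) / sum(m), numeric(1))
}

#' Determine the SLE onset region from ROI time courses
#'
#' The onset region is the one whose ROI time course first crosses
#' `onset_threshold_pct` after the control window. Ties (same crossing frame)
#' are broken by the larger dT/T at the crossing frame, then by the fixed
#' region order SUB, EC, PC, TC.
#'
#' @param dtt a `dtt_stack`.
#' @param masks region masks (default: carried in `dtt`).
#' @param onset_threshold_pct crossing threshold, percent; default 0.4 (the
#'   lower bound of typical ictal ROI dT/T).
#' @param roi_size ROI edge in pixels.
#' @return region label, or `NA_character_` if no region crosses.
#' @export
onset_region <- function(dtt, masks = dtt$masks, onset_threshold_pct = 0.4,
                         roi_size = 20L) {
  tc <- roi_intensity(dtt, masks, roi_size)$time_course
  post <- seq.int(dtt$n_control_frames + 1L, ncol(tc))
  cross <- apply(tc[, post, drop = FALSE], 1L, function(v) {
    i <- which(v >= onset_threshold_pct)
    if (length(i)) i[1L] else NA_integer_
  })
  if (all(is.na(cross))) return(NA_character_)
  cand <- names(cross)[which(cross == min(cross, na.rm = TRUE))]
  if (length(cand) > 1L) {
    at <- tc[cand, post[min(cross, na.rm = TRUE)]]
    cand <- cand[order(-at, match(cand, REGIONS))]
  }
  cand[1L]
}

#' Render a dT/T stack as deterministic pseudocolor frames
#'
#' Writes one binary PPM (P6) image per frame plus a JSON index, with a fixed
#' colour scale and an embedded vertical scale bar. PPM output is
#' byte-reproducible for identical input, which keeps rendered videos
#' verifiable; PPM sequences convert directly to video with standard tools.
#'
#' @param dtt a `dtt_stack`.
#' @param out_dir output directory (created if missing).
#' @param range dT/T range mapped onto the colour scale, percent.
#' @return invisible character vector of frame file paths.
#' @export
render_pseudocolor <- function(dtt, out_dir, range = c(-1, 4)) {
  stopifnot(inherits(dtt, "dtt_stack"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2L) != 0L) stop("unwritable path: ", out_dir)
  pal <- grDevices::colorRamp(c("#000080", "#0000ff", "#00ffff",
                                "#ffff00", "#ff0000"))
  lut <- round(pal(seq(0, 1, length.out = 256)))  # 256 x 3
  d <- dtt$dtt
  h <- dim(d)[1L]; w <- dim(d)[2L]; n <- dim(d)[3L]
  barw <- 12L
  bar_col <- rev(as.integer(round(seq(1, 256, length.out = h))))
  paths <- character(n)
  for (f in seq_len(n)) {
    v <- d[, , f]
    v <- (v - range[1L]) / (range[2L] - range[1L])
    idx <- as.integer(round(pmin(pmax(v, 0), 1) * 255)) + 1L
    idx[is.na(idx)] <- 1L
    img <- matrix(0L, h, (w + barw) * 3L)
    rgb <- lut[idx, , drop = FALSE]               # (h*w) x 3
    full <- array(0L, dim = c(h, w + barw, 3L))
    for (ch in 1:3) {
      full[, seq_len(w), ch] <- matrix(rgb[, ch], h, w)
      full[, w + seq_len(barw), ch] <- matrix(lut[bar_col, ch], h, barw)
    }
    # P6: rows top to bottom, RGB interleaved
    payload <- as.raw(aperm(full, c(3L, 2L, 1L)))
    paths[f] <- file.path(out_dir, sprintf("frame_%04d.ppm", f))
    con <- file(paths[f], "wb")
    writeChar(sprintf("P6\n%d %d\n255\n", w + barw, h), con, eos = NULL)
    writeBin(payload, con)
    close(con)
  }
  jsonlite::write_json(
    list(n_frames = n, width = w + barw, height = h,
         scale_range_pct = range, frame_times_s = dtt$frame_times_s),
    file.path(out_dir, "frames.json"), auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
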