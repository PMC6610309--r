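# Procedural anatomical region masks on the 320 x 240 camera frame.

#' Generate the anatomical region mask set
#'
#' Draws four mutually disjoint masks (SUB, EC, PC, TC) as angular sectors of
#' an elliptical annulus on the 320 x 240 imaging frame, mimicking the layout
#' of a horizontal hippocampal-entorhinal slice viewed at low magnification:
#' the cortical ribbon wraps around the slice and the subiculum occupies a
#' deliberately small sector between hippocampus and entorhinal cortex.
#'
#' @param width,height frame size in pixels (camera default 320 x 240).
#' @return object of class `region_mask_set`: a named list of logical
#'   `height x width` matrices (`SUB`, `EC`, `PC`, `TC`), mutually disjoint,
#'   each non-empty, with `SUB` the smallest.
#' @export
region_masks <- function(width = 320L, height = 240L) {
  stopifnot(width >= 40L, height >= 40L)
  cx <- width * 0.5; cy <- height * 0.52
  x <- matrix(rep(seq_len(width), each = height), nrow = height)
  y <- matrix(rep(seq_len(height), times = width), nrow = height)
  # normalized elliptical radius and angle
  rr <- sqrt(((x - cx) / (width * 0.46))^2 + ((y - cy) / (height * 0.44))^2)
  th <- atan2(y - cy, x - cx) * 180 / pi  # (-180, 180], 0 = +x axis
  ribbon <- rr > 0.30 & rr <= 1.0
  sector <- function(a, b) ribbon & th >= a & th < b
  masks <- list(
    SUB = sector(-20, 12),    # small wedge
    EC  = sector(12, 110),
    PC  = sector(110, 185) | (ribbon & th < -160),
    TC  = sector(-160, -20)
  )
  stopifnot(all(vapply(masks, any, logical(1))))
  structure(masks, class = "region_mask_set",
            frame_dim = c(height = height, width = width))
}

#' @export
print.region_mask_set <- function(x, ...) {
  d <- attr(x, "frame_dim")
  cat(sprintf("<region_mask_set> %d x %d frame\n", d["width"], d["height"]))
  for (r in names(x)) cat(sprintf("  %-3s %6d px\n", r, sum(x[[r]])))
  invisible(x)
}

#' Write region masks as a labelled single-page TIFF
#'
#' Pixel values 0 (background), 1..4 for `SUB`, `EC`, `PC`, `TC`; the label
#' legend goes to a JSON sidecar.
#'
#' @param masks a [region_masks] set.
#' @param path output TIFF path; the sidecar gets extension `.labels.json`.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(masks, path) {
  lab <- masks[[1L]] * 0L
  for (i in seq_along(masks)) lab[masks[[i]]] <- i
  write_tiff_stack(array(lab, dim = c(dim(lab), 1L)), path)
  jsonlite::write_json(as.list(stats::setNames(seq_along(masks), names(masks))),
                       sub("\\.tiff?$", ".labels.json", path,
                           ignore.case = TRUE),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read region masks from a labelled TIFF written by [write_mask_tiff]
#' @param path TIFF path.
#' @return a `region_mask_set`.
#' @export
read_mask_tiff <- function(path) {
  lab <- read_tiff_stack(path)[, , 1L]
  legend <- jsonlite::read_json(sub("\\.tiff?$", ".labels.json", path,
                                    ignore.case = TRUE))
  masks <- lapply(legend, function(i) lab == i)
  structure(masks, class = "region_mask_set",
            frame_dim = c(height = nrow(lab), width = ncol(lab)))
}
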