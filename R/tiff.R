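# Minimal multi-page TIFF I/O for 8-bit grayscale stacks.
#
# No TIFF package ships with this toolchain, and the IOS stacks only need the
# simplest corner of the format: uncompressed, 8-bit, single-sample,
# little-endian, one strip per page. Writing that subset directly keeps the
# on-disk format standard (readable by ImageJ/tifffile) without a dependency.

TIFF_TYPE_SHORT <- 3L
TIFF_TYPE_LONG  <- 4L

tiff_entry <- function(tag, type, count, value) {
  con <- raw(0)
  c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    if (type == TIFF_TYPE_SHORT)
      c(writeBin(as.integer(value), raw(), size = 2, endian = "little"),
        as.raw(c(0, 0)))
    else
      writeBin(as.integer(value), raw(), size = 4, endian = "little"))
}

#' Write an 8-bit grayscale multi-page TIFF
#'
#' @param stack numeric or integer array `height x width x n_frames` with
#'   values in \[0, 255\] (fractional values are rounded).
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_tiff_stack()]
#' @export
write_tiff_stack <- function(stack, path) {
  if (length(dim(stack)) == 2L) dim(stack) <- c(dim(stack), 1L)
  stopifnot(length(dim(stack)) == 3L)
  if (any(!is.finite(stack)) || any(stack < -0.5) || any(stack > 255.5))
    stop("stack values must be finite and within [0, 255]")
  h <- dim(stack)[1L]; w <- dim(stack)[2L]; n <- dim(stack)[3L]
  vals <- as.integer(round(stack))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  # layout per page: [pixel data][IFD]; header points at first IFD
  page_bytes <- h * w
  ifd_bytes <- 2L + 8L * 12L + 4L
  first_ifd <- 8L + page_bytes
  writeBin(first_ifd, con, size = 4, endian = "little")

  offset <- 8L
  for (p in seq_len(n)) {
    frame <- matrix(vals[((p - 1L) * page_bytes + 1L):(p * page_bytes)], h, w)
    writeBin(as.raw(as.vector(t(frame))), con)   # row-major strip
    data_off <- offset
    ifd_off <- offset + page_bytes
    next_ifd <- if (p < n) ifd_off + ifd_bytes + page_bytes else 0L
    writeBin(8L, con, size = 2, endian = "little")  # entry count
    writeBin(c(
      tiff_entry(256L, TIFF_TYPE_LONG, 1L, w),        # ImageWidth
      tiff_entry(257L, TIFF_TYPE_LONG, 1L, h),        # ImageLength
      tiff_entry(258L, TIFF_TYPE_SHORT, 1L, 8L),      # BitsPerSample
      tiff_entry(259L, TIFF_TYPE_SHORT, 1L, 1L),      # Compression: none
      tiff_entry(262L, TIFF_TYPE_SHORT, 1L, 1L),      # Photometric: min-is-black
      tiff_entry(273L, TIFF_TYPE_LONG, 1L, data_off), # StripOffsets
      tiff_entry(278L, TIFF_TYPE_LONG, 1L, h),        # RowsPerStrip
      tiff_entry(279L, TIFF_TYPE_LONG, 1L, page_bytes)), con)  # StripByteCounts
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    offset <- ifd_off + ifd_bytes
  }
  invisible(path)
}

read_uint <- function(r, pos, size, endian = "little") {
  if (size == 4L) {  # readBin is signed at size 4; our offsets stay < 2^31
    v <- readBin(r[pos:(pos + 3L)], "integer", size = 4, endian = endian)
    if (v < 0) stop("TIFF offset exceeds 2 GiB; unsupported")
    return(v)
  }
  readBin(r[pos:(pos + size - 1L)], "integer", size = size,
          endian = endian, signed = FALSE)
}

#' Read an 8-bit grayscale multi-page TIFF
#'
#' Supports the uncompressed baseline subset written by [write_tiff_stack()]
#' (either byte order, one or more strips per page).
#'
#' @param path TIFF file path.
#' @return integer array `height x width x n_frames`, values 0-255.
#' @export
read_tiff_stack <- function(path) {
  r <- readBin(path, "raw", file.info(path)$size)
  endian <- if (rawToChar(r[1:2]) == "II") "little" else "big"
  if (read_uint(r, 3L, 2L, endian) != 42L) stop("not a TIFF file: ", path)
  ifd <- read_uint(r, 5L, 4L, endian)
  frames <- list()
  while (ifd != 0L) {
    n_entries <- read_uint(r, ifd + 1L, 2L, endian)
    needed <- c(256L, 257L, 258L, 259L, 262L, 273L, 277L, 278L, 279L)
    tags <- list()
    for (i in seq_len(n_entries)) {
      e <- ifd + 3L + (i - 1L) * 12L
      tag <- read_uint(r, e, 2L, endian)
      if (!tag %in% needed) next    # descriptions, resolutions, etc.
      type <- read_uint(r, e + 2L, 2L, endian)
      if (!type %in% c(TIFF_TYPE_SHORT, TIFF_TYPE_LONG))
        stop("unsupported TIFF tag type ", type, " for tag ", tag)
      count <- read_uint(r, e + 4L, 4L, endian)
      size <- if (type == TIFF_TYPE_SHORT) 2L else 4L
      at <- if (count * size <= 4L) e + 8L else
        read_uint(r, e + 8L, 4L, endian) + 1L
      tags[[as.character(tag)]] <- vapply(
        seq_len(count) - 1L,
        function(k) read_uint(r, at + size * k, size, endian), 0L)
    }
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags))) stop("TIFF page missing required tags")
    if ((tags[["259"]] %||% 1L)[1L] != 1L) stop("compressed TIFF unsupported")
    if ((tags[["258"]] %||% 8L)[1L] != 8L) stop("only 8-bit TIFF supported")
    w <- tags[["256"]][1L]; h <- tags[["257"]][1L]
    bytes <- unlist(mapply(function(o, nb) r[(o + 1L):(o + nb)],
                           tags[["273"]], tags[["279"]], SIMPLIFY = FALSE))
    px <- as.integer(bytes)
    frames[[length(frames) + 1L]] <- t(matrix(px, nrow = w, ncol = h))
    ifd <- read_uint(r, ifd + 3L + n_entries * 12L, 4L, endian)
  }
  arr <- array(0L, dim = c(dim(frames[[1L]]), length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- frames[[i]]
  arr
}
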