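# Plain-text interchange: trace CSV + JSON sidecar, event tables, manifests.

#' Write an LFP trace as CSV with a JSON metadata sidecar
#'
#' The CSV holds `time_s, voltage_mV`; sampling rate, phase windows and
#' metadata go to `<path>.meta.json`.
#'
#' @param trace an [lfp_trace].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_lfp_csv <- function(trace, path) {
  stopifnot(inherits(trace, "lfp_trace"))
  n <- length(trace$samples)
  utils::write.csv(
    data.frame(time_s = round((seq_len(n) - 1L) / trace$fs, 6L),
               voltage_mV = round(trace$samples, 6L)),
    path, row.names = FALSE)
  meta <- list(sampling_rate_hz = trace$fs,
               phases = trace$phases, metadata = trace$metadata)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an LFP trace written by [write_lfp_csv]
#' @param path CSV path (expects `<path>.meta.json` beside it).
#' @return an [lfp_trace].
#' @export
read_lfp_csv <- function(path) {
  d <- utils::read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) stop("missing metadata sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  phases <- meta$phases
  if (!is.null(phases)) phases <- as.data.frame(phases)
  lfp_trace(d$voltage_mV, meta$sampling_rate_hz, phases,
            as.list(meta$metadata))
}

#' Write a detected event table as CSV and JSON
#' @param events an `sle_events` data.frame.
#' @param stem output path stem; writes `<stem>.csv` and `<stem>.json`.
#' @return invisible character vector of the two paths.
#' @export
write_events <- function(events, stem) {
  csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
  utils::write.csv(as.data.frame(events), csv, row.names = FALSE)
  jsonlite::write_json(as.data.frame(events), js, digits = NA, null = "null")
  invisible(c(csv, js))
}

#' Write ground truth to JSON
#' @param ground_truth data.frame from [generate_lfp].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, digits = NA, null = "null")
  invisible(path)
}
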