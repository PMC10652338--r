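# File interchange: traces (raw little-endian float32 + JSON sidecar, or
# single-column CSV), images (one CSV per channel/z-plane + JSON metadata; the
# environment provides no TIFF codec, so the on-disk container is plain text
# with the same information content), truth sidecars and reports as JSON.

#' Write / read an ionic-current trace
#'
#' `write_trace_raw` stores samples as little-endian 32-bit floats in
#' `<stem>.f32` with a JSON metadata sidecar `<stem>.json` (sampling_hz,
#' voltage_mv, acq_filter_hz, source). `write_trace_csv` writes a
#' single-column CSV (`current_pa`) plus the same sidecar.
#'
#' @param trace a [current_trace()].
#' @param stem output path without extension.
#' @return the stem, invisibly.
#' @export
write_trace_raw <- function(trace, stem) {
  stopifnot(inherits(trace, "current_trace"))
  con <- file(paste0(stem, ".f32"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(trace$samples), con, size = 4L, endian = "little")
  .write_trace_sidecar(trace, stem)
  invisible(stem)
}

.write_trace_sidecar <- function(trace, stem) {
  jsonlite::write_json(list(sampling_hz = trace$sampling_hz,
                            voltage_mv = trace$voltage_mv,
                            acq_filter_hz = trace$acq_filter_hz,
                            source = trace$source),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
}

#' @rdname write_trace_raw
#' @export
read_trace_raw <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"))
  path <- paste0(stem, ".f32")
  n <- file.info(path)$size / 4L
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  current_trace(x, sampling_hz = as.numeric(meta$sampling_hz),
                voltage_mv = meta$voltage_mv %||% NA_real_,
                acq_filter_hz = meta$acq_filter_hz %||% NA_real_,
                source = meta$source %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_trace_raw
#' @export
write_trace_csv <- function(trace, stem) {
  stopifnot(inherits(trace, "current_trace"))
  utils::write.csv(data.frame(current_pa = trace$samples),
                   paste0(stem, ".csv"), row.names = FALSE)
  .write_trace_sidecar(trace, stem)
  invisible(stem)
}

#' @rdname write_trace_raw
#' @export
read_trace_csv <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"))
  x <- utils::read.csv(paste0(stem, ".csv"))$current_pa
  current_trace(x, sampling_hz = as.numeric(meta$sampling_hz),
                voltage_mv = meta$voltage_mv %||% NA_real_,
                acq_filter_hz = meta$acq_filter_hz %||% NA_real_,
                source = meta$source %||% "")
}

#' Write / read a multi-channel COC image as plain text
#'
#' One headerless CSV per channel and z-plane
#' (`<stem>_<channel>_z<k>.csv`) plus a JSON metadata file `<stem>.json`
#' (pixel_size_um, channel names, z_count, shape).
#'
#' @param image a [coc_image()].
#' @param stem output path stem.
#' @return the stem, invisibly.
#' @export
write_coc_image <- function(image, stem) {
  stopifnot(inherits(image, "coc_image"))
  for (nm in names(image$channels)) {
    for (z in seq_len(image$z_count)) {
      utils::write.table(.plane(image$channels[[nm]], z),
                         sprintf("%s_%s_z%d.csv", stem, nm, z),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
  }
  d <- dim(image$channels[[1L]])[1:2]
  jsonlite::write_json(list(pixel_size_um = image$pixel_size_um,
                            channels = names(image$channels),
                            z_count = image$z_count,
                            shape_px = d),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_coc_image
#' @export
read_coc_image <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  channels <- lapply(meta$channels, function(nm) {
    planes <- lapply(seq_len(meta$z_count), function(z) {
      as.matrix(utils::read.table(sprintf("%s_%s_z%d.csv", stem, nm, z),
                                  sep = ","))
    })
    arr <- simplify2array(planes)
    dimnames(arr) <- NULL
    arr
  })
  names(channels) <- meta$channels
  coc_image(channels, pixel_size_um = meta$pixel_size_um)
}

#' Write detected events and polydispersity reports
#'
#' @param events mapped events data.frame (from [map_mw()]).
#' @param path output CSV path.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @param poly a `polydispersity_result`.
#' @export
write_polydispersity_json <- function(poly, path) {
  stopifnot(inherits(poly, "polydispersity_result"))
  jsonlite::write_json(list(
    n_events = poly$n_events,
    weighted_avg_mw_kda = poly$weighted_avg_mw_kda,
    number_avg_mw_kda = poly$number_avg_mw_kda,
    fraction_below = as.list(poly$fraction_below),
    qc_pass = poly$qc_pass,
    histogram = poly$histogram
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read an event ground-truth sidecar
#'
#' @param truth data.frame from [gen_trace()].
#' @param path JSON path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
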