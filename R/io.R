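#' Write a recording as flat binary samples plus a JSON sidecar
#'
#' The native on-disk container: a raw little-endian sample file
#' (`<path>.bin`, channel-contiguous) and a JSON sidecar (`<path>.json`)
#' declaring sampling rate, shape, dtype and the multiplicative scale that
#' converts stored values to uV.
#'
#' @param rec an `mea_recording`
#' @param path file stem; `.bin` and `.json` are appended
#' @param dtype storage type, `"float64"` (default) or `"float32"`
#' @return `path`, invisibly
#' @export
write_recording <- function(rec, path, dtype = c("float64", "float32")) {
  stopifnot(inherits(rec, "mea_recording"))
  dtype <- match.arg(dtype)
  size <- if (dtype == "float64") 8L else 4L
  meta <- list(
    format = "meacircuit-recording", version = 1L,
    fs = rec$fs, n_channels = nrow(rec$data), n_samples = ncol(rec$data),
    dtype = dtype, byte_order = "little", order = "channel-major",
    unit = "uV", scale_to_uv = 1,
    channel_ids = rec$channel_ids, t0 = rec$t0,
    layout_ref = rec$layout_ref, meta = rec$meta
  )
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  # t() makes each channel's trace contiguous in the column-major stream
  writeBin(as.vector(t(rec$data)), con, size = size, endian = "little")
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a recording
#'
#' Reads the flat-binary + JSON sidecar dialect written by
#' [write_recording()]. Stored values are rescaled to uV via the sidecar's
#' `scale_to_uv` field, so containers holding e.g. mV read back correctly.
#'
#' @param path file stem (or the `.json` sidecar path)
#' @param format container dialect; only `"flat-binary+json"` is supported
#'   by this build
#' @return an `mea_recording` in uV
#' @export
read_recording <- function(path, format = c("flat-binary+json", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5") {
    stop("HDF5 container reading is not available in this build; ",
         "use the flat-binary + JSON sidecar dialect")
  }
  path <- sub("\\.json$", "", sub("\\.bin$", "", path))
  json_path <- paste0(path, ".json")
  bin_path <- paste0(path, ".bin")
  if (!file.exists(json_path)) stop("sidecar not found: ", json_path)
  if (!file.exists(bin_path)) stop("sample file not found: ", bin_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  required <- c("fs", "n_channels", "n_samples", "dtype", "scale_to_uv",
                "channel_ids")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("sidecar is missing metadata keys: ", paste(missing, collapse = ", "))
  }
  size <- switch(meta$dtype, float64 = 8L, float32 = 4L,
                 stop("unknown dtype: ", meta$dtype))
  n_expect <- as.integer(meta$n_channels) * as.integer(meta$n_samples)
  n_bytes <- file.info(bin_path)$size
  if (n_bytes != n_expect * size) {
    stop("sample file size (", n_bytes, " bytes) does not match declared ",
         meta$n_channels, " x ", meta$n_samples, " ", meta$dtype, " samples")
  }
  con <- file(bin_path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n_expect, size = size, endian = "little")
  if (any(!is.finite(x))) stop("sample file contains NaN/Inf values")
  mat <- t(matrix(x, nrow = meta$n_samples, ncol = meta$n_channels))
  recording(mat * meta$scale_to_uv, fs = meta$fs,
            channel_ids = as.character(meta$channel_ids),
            t0 = meta$t0 %||% 0, layout_ref = meta$layout_ref,
            meta = as.list(meta$meta %||% list()))
}

#' Write a metrics table as delimited text
#'
#' One row per measurement, header included, columns in the order given.
#'
#' @param results a data.frame (any stage output flattened to rows)
#' @param path output file path (CSV)
#' @return `path`, invisibly
#' @export
write_metrics <- function(results, path) {
  stopifnot(is.data.frame(results))
  write.csv(results, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a metrics table written by [write_metrics()]
#' @param path CSV path
#' @return data.frame
#' @export
read_metrics <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a spike-train set to JSON
#' @param sts an `mea_spiketrains`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_spike_trains <- function(sts, path) {
  stopifnot(inherits(sts, "mea_spiketrains"))
  jsonlite::write_json(
    list(format = "meacircuit-spiketrains", duration = sts$duration,
         channel_ids = sts$channel_ids, trains = sts$trains),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a spike-train set written by [write_spike_trains()]
#' @param path JSON path
#' @return an `mea_spiketrains`
#' @export
read_spike_trains <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  trains <- lapply(x$trains, as.numeric)
  spike_train_set(trains[x$channel_ids], duration = x$duration,
                  channel_ids = as.character(x$channel_ids))
}

#' Write a circuit layout to JSON
#' @param layout an `mea_layout`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "mea_layout"))
  jsonlite::write_json(
    list(format = "meacircuit-layout", pitch = layout$pitch,
         positions = layout$positions, paths = layout$paths,
         segments = layout$segments),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a circuit layout written by [write_layout()]
#' @param path JSON path
#' @return an `mea_layout`
#' @export
read_layout <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  segments <- x$segments
  if (!is.null(segments) && is.data.frame(segments)) segments <- list(segments)
  paths <- x$paths
  if (!is.list(paths)) paths <- list(paths)
  paths <- lapply(paths, as.character)
  circuit_layout(x$positions, paths, segments = segments, pitch = x$pitch)
}
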