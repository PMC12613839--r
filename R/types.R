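#' Construct a multichannel extracellular recording
#'
#' The core container of the pipeline: a channels x samples matrix of voltage
#' in microvolts together with its sampling rate and channel identity.
#'
#' @param data numeric matrix, channels x samples, in uV
#' @param fs sampling rate in Hz (> 0)
#' @param channel_ids character vector, one id per row of `data`
#' @param t0 recording start time in seconds
#' @param layout_ref optional identifier of the associated circuit layout
#' @param meta optional named list of provenance fields (input path,
#'   parameters, seed) carried through the pipeline
#' @return an object of class `mea_recording`
#' @export
recording <- function(data, fs, channel_ids = NULL, t0 = 0, layout_ref = NULL,
                      meta = list()) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix (channels x samples)")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)")
  }
  if (any(!is.finite(data))) stop("voltage samples must be finite")
  if (is.null(channel_ids)) {
    channel_ids <- rownames(data) %||% paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_ids) != nrow(data)) {
    stop("`channel_ids` length (", length(channel_ids),
         ") != channel count (", nrow(data), ")")
  }
  rownames(data) <- channel_ids
  structure(
    list(data = data, fs = fs, channel_ids = as.character(channel_ids),
         t0 = t0, layout_ref = layout_ref, meta = meta),
    class = "mea_recording"
  )
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording> %d channels x %d samples @ %g Hz (%.3f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `mea_recording`
#' @return duration (s)
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

#' Construct a circuit layout
#'
#' Electrode geometry of a microchannel circuit: positions on the MEA grid,
#' ordered electrode paths along microchannels, and labelled distance segments
#' within each path (e.g. "individual" axon span vs "bundled" spans).
#'
#' @param positions data.frame with columns `channel_id`, `x`, `y` (um)
#' @param paths list of character vectors; each an ordered electrode sequence
#'   along one microchannel
#' @param segments list (one element per path) of data.frames with columns
#'   `label`, `start_um`, `end_um`: non-overlapping distance ranges measured
#'   along the path from its first electrode
#' @param pitch nominal electrode spacing in um
#' @return an object of class `mea_layout`
#' @export
circuit_layout <- function(positions, paths, segments = NULL, pitch = 200) {
  stopifnot(is.data.frame(positions),
            all(c("channel_id", "x", "y") %in% names(positions)))
  positions$channel_id <- as.character(positions$channel_id)
  if (!is.list(paths)) paths <- list(paths)
  for (p in paths) {
    if (length(p) == 0L) stop("empty electrode path")
    if (!all(p %in% positions$channel_id)) {
      stop("path references unknown channel ids: ",
           paste(setdiff(p, positions$channel_id), collapse = ", "))
    }
    if (length(p) >= 2L) {
      d <- path_distances(positions, p)
      if (any(d <= 0)) stop("consecutive path electrodes must be separated")
    }
  }
  if (!is.null(segments)) {
    if (is.data.frame(segments)) segments <- list(segments)
    for (s in segments) {
      stopifnot(all(c("label", "start_um", "end_um") %in% names(s)))
      s <- s[order(s$start_um), ]
      if (any(s$end_um <= s$start_um)) stop("segment ranges must have end > start")
      if (nrow(s) > 1L && any(s$start_um[-1L] < s$end_um[-nrow(s)])) {
        stop("segment distance ranges overlap within a path")
      }
    }
  }
  structure(
    list(positions = positions, paths = paths, segments = segments,
         pitch = pitch),
    class = "mea_layout"
  )
}

#' @export
print.mea_layout <- function(x, ...) {
  cat(sprintf("<mea_layout> %d electrodes, %d path(s), pitch %g um\n",
              nrow(x$positions), length(x$paths), x$pitch))
  invisible(x)
}

#' Distances between consecutive electrodes along a path
#'
#' @param positions positions data.frame (or an `mea_layout`)
#' @param path character vector of channel ids in path order
#' @return numeric vector of consecutive distances (um); empty for a
#'   single-electrode path
#' @export
path_distances <- function(positions, path) {
  if (inherits(positions, "mea_layout")) positions <- positions$positions
  if (length(path) < 2L) return(numeric(0))
  idx <- match(path, positions$channel_id)
  dx <- diff(positions$x[idx])
  dy <- diff(positions$y[idx])
  sqrt(dx^2 + dy^2)
}

#' Cumulative distance of each path electrode from the path start
#' @inheritParams path_distances
#' @return numeric vector, one entry per path electrode (first = 0)
#' @export
path_cumdist <- function(positions, path) {
  c(0, cumsum(path_distances(positions, path)))
}

#' Segment label at a given distance along a path
#'
#' @param segments data.frame with `label`, `start_um`, `end_um`
#' @param dist_um distance(s) along the path (um)
#' @return character vector of labels (NA where no segment covers the point)
#' @export
segment_at <- function(segments, dist_um) {
  out <- rep(NA_character_, length(dist_um))
  for (i in seq_len(nrow(segments))) {
    hit <- dist_um >= segments$start_um[i] & dist_um < segments$end_um[i]
    out[hit] <- segments$label[i]
  }
  # points exactly at the final boundary belong to the last segment
  last <- which.max(segments$end_um)
  out[dist_um == segments$end_um[last]] <- segments$label[last]
  out
}

#' Construct a set of spike trains
#'
#' @param trains named list of numeric vectors: strictly increasing spike
#'   times in seconds, one element per channel (or neuron)
#' @param duration recording length in seconds
#' @param channel_ids optional ids; defaults to `names(trains)`
#' @return an object of class `mea_spiketrains`
#' @export
spike_train_set <- function(trains, duration, channel_ids = NULL) {
  if (is.null(channel_ids)) {
    channel_ids <- names(trains) %||% paste0("ch", seq_along(trains))
  }
  stopifnot(length(channel_ids) == length(trains),
            is.numeric(duration), duration > 0)
  for (i in seq_along(trains)) {
    tr <- trains[[i]]
    if (length(tr) == 0L) next
    if (any(tr < 0 | tr > duration)) {
      stop("spike times outside [0, duration] on channel ", channel_ids[i])
    }
    if (any(diff(tr) <= 0)) {
      stop("spike times must be strictly increasing on channel ", channel_ids[i])
    }
  }
  names(trains) <- channel_ids
  structure(list(trains = trains, duration = duration,
                 channel_ids = as.character(channel_ids)),
            class = "mea_spiketrains")
}

#' @export
print.mea_spiketrains <- function(x, ...) {
  n <- vapply(x$trains, length, integer(1))
  cat(sprintf("<mea_spiketrains> %d trains, %d spikes total, %.3f s\n",
              length(x$trains), sum(n), x$duration))
  invisible(x)
}

#' Pair of spike-train sets for a condition comparison
#'
#' Holds matched baseline and treated (e.g. synaptic-blocker) spike trains of
#' the same circuit for interspike-interval divergence analysis.
#'
#' @param baseline,treated `mea_spiketrains` with matching channel ids
#' @param label condition name, e.g. "NBQX+AP5" or "CBX"
#' @return an object of class `mea_condition_pair`
#' @export
condition_pair <- function(baseline, treated, label = "treated") {
  stopifnot(inherits(baseline, "mea_spiketrains"),
            inherits(treated, "mea_spiketrains"))
  if (!identical(baseline$channel_ids, treated$channel_ids)) {
    stop("channel ids of baseline and treated spike-train sets must match")
  }
  structure(list(baseline = baseline, treated = treated, label = label),
            class = "mea_condition_pair")
}
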