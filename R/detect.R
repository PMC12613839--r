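#' Robust noise level of a trace via the median absolute deviation
#'
#' `median(|x - median(x)|) * 1.4826`: the MAD scaled to be a consistent
#' estimator of the Gaussian SD. The robust estimator lets the noise level
#' be computed on the full trace, spikes included, at the sparse firing
#' rates of these circuits. Set `scale = 1` for the raw (unscaled) MAD.
#'
#' @param trace numeric vector of samples (uV), length >= 2
#' @param scale multiplicative constant; 1.4826 (default) for normal
#'   consistency
#' @return noise level in uV
#' @export
noise_level_mad <- function(trace, scale = 1.4826) {
  if (length(trace) < 2L) stop("need at least 2 samples")
  median(abs(trace - median(trace))) * scale
}

#' Detect spike peaks as a data.frame
#'
#' Threshold detection on each channel of a preprocessed recording: a sample
#' is a peak iff its (signed) value crosses `k_mad` times the scaled MAD and
#' it is the extremum within `+/- exclude_sweep_ms`; ties inside the sweep go
#' to the earliest sample. Default criteria: negative signs only, threshold
#' 5 x MAD, 0.2 ms exclusion sweep.
#'
#' @param rec an `mea_recording` (preprocessed)
#' @param k_mad threshold in scaled-MAD units (> 0)
#' @param exclude_sweep_ms half-width of the local-extremum exclusion
#'   window (ms)
#' @param sign `"neg"`, `"pos"` or `"both"`
#' @param mad_scale MAD scaling constant (1.4826, or 1 for raw MAD)
#' @return data.frame: `channel`, `t` (s, at the peak sample), `amp_uv`
#'   (signed peak value), `sample`
#' @export
detect_peaks_frame <- function(rec, k_mad = 5, exclude_sweep_ms = 0.2,
                               sign = c("neg", "pos", "both"),
                               mad_scale = 1.4826) {
  stopifnot(inherits(rec, "mea_recording"))
  if (k_mad <= 0) stop("`k_mad` must be > 0")
  sign <- match.arg(sign)
  sweep_n <- as.integer(round(exclude_sweep_ms / 1000 * rec$fs))
  rows <- vector("list", nrow(rec$data))
  for (ch in seq_len(nrow(rec$data))) {
    x <- rec$data[ch, ]
    thr <- k_mad * noise_level_mad(x, scale = mad_scale)
    idx <- integer(0)
    if (sign %in% c("neg", "both")) {
      idx <- c(idx, local_extrema(x, -thr, sweep_n, negative = TRUE))
    }
    if (sign %in% c("pos", "both")) {
      idx <- c(idx, local_extrema(x, thr, sweep_n, negative = FALSE))
    }
    idx <- sort(unique(idx))
    if (length(idx)) {
      rows[[ch]] <- data.frame(channel = rec$channel_ids[ch],
                               t = sample_to_time(idx, rec$fs, rec$t0),
                               amp_uv = x[idx], sample = idx)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(channel = character(0), t = numeric(0),
                      amp_uv = numeric(0), sample = integer(0))
  }
  rownames(out) <- NULL
  out
}

# Indices of samples beyond `thr` that are the extremum within +/- sweep_n
# samples (earliest sample wins ties).
local_extrema <- function(x, thr, sweep_n, negative) {
  if (negative) {
    cand <- which(x < thr)
  } else {
    cand <- which(x > thr)
  }
  if (!length(cand)) return(integer(0))
  n <- length(x)
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    lo <- max(1L, i - sweep_n)
    hi <- min(n, i + sweep_n)
    win <- x[lo:hi]
    ext <- if (negative) min(win) else max(win)
    if (x[i] == ext && (lo - 1L + which(win == ext)[1L]) == i) keep[k] <- TRUE
  }
  cand[keep]
}

#' Detect spikes as per-electrode spike trains
#'
#' Wrapper around [detect_peaks_frame()] returning the timestamps as an
#' `mea_spiketrains`, the form consumed by the dynamics stage.
#'
#' @inheritParams detect_peaks_frame
#' @return an `mea_spiketrains` with one (possibly empty) train per channel
#' @export
detect_spikes <- function(rec, k_mad = 5, exclude_sweep_ms = 0.2,
                          sign = c("neg", "pos", "both"),
                          mad_scale = 1.4826) {
  pk <- detect_peaks_frame(rec, k_mad = k_mad,
                           exclude_sweep_ms = exclude_sweep_ms,
                           sign = match.arg(sign), mad_scale = mad_scale)
  dur <- recording_duration(rec)
  trains <- lapply(rec$channel_ids, function(ch) {
    tt <- sort(pk$t[pk$channel == ch]) - rec$t0
    tt[tt >= 0 & tt <= dur]
  })
  names(trains) <- rec$channel_ids
  spike_train_set(trains, duration = dur, channel_ids = rec$channel_ids)
}
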