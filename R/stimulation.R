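#' Blank electrical stimulation artifacts
#'
#' Replaces the samples within `+/- blank_ms` of every stimulus onset by
#' linear interpolation between the span boundaries, on every channel, so
#' the large biphasic stimulation transient cannot masquerade as spikes.
#'
#' @param rec an `mea_recording`
#' @param onsets stimulus onset times (s)
#' @param blank_ms half-width of the blanked span (ms)
#' @return blanked `mea_recording`
#' @export
blank_stim_artifacts <- function(rec, onsets, blank_ms = 2) {
  stopifnot(inherits(rec, "mea_recording"))
  n <- ncol(rec$data)
  for (on in onsets) {
    i0 <- max(1L, time_to_sample(on - blank_ms / 1000, rec$fs, rec$t0))
    i1 <- min(n, time_to_sample(on + blank_ms / 1000, rec$fs, rec$t0))
    if (i1 <= i0) next
    lo <- i0 - 1L
    hi <- i1 + 1L
    for (ch in seq_len(nrow(rec$data))) {
      # spans clipped at a trace edge have only one clean boundary: fill flat
      v_lo <- if (lo >= 1L) rec$data[ch, lo] else rec$data[ch, min(n, hi)]
      v_hi <- if (hi <= n) rec$data[ch, hi] else rec$data[ch, max(1L, lo)]
      rec$data[ch, i0:i1] <- seq(v_lo, v_hi,
                                 length.out = i1 - i0 + 3L)[2:(i1 - i0 + 2L)]
    }
  }
  rec$meta$blanked <- list(blank_ms = blank_ms, n_onsets = length(onsets))
  rec
}

#' Extract evoked responses to a stimulus train
#'
#' For every stimulus onset, collects the detected AP peaks on all channels
#' within `(onset, onset + window_ms]` and keeps only peaks whose amplitude
#' magnitude exceeds `min_amp_uv` (artifact exclusion). When response
#' windows would overlap the next onset (high-frequency trains) they are
#' truncated at that onset and flagged. Stimuli without any surviving peak
#' are retained as failures.
#'
#' @param rec preprocessed `mea_recording`
#' @param stims data.frame with an `onset` column (s), e.g. the `stim`
#'   element of [simulate_stim_protocol()], or a numeric onset vector
#' @param window_ms response window after each onset (ms)
#' @param min_amp_uv amplitude gate: peaks with |amplitude| <= this are
#'   dropped
#' @param peaks optional precomputed [detect_peaks_frame()] output
#' @param ... passed to [detect_peaks_frame()] when `peaks` is NULL
#' @return list: `aps` (data.frame stim_index, channel, t, latency_ms,
#'   amp_uv) and `stims` (data.frame stim_index, onset, n_aps,
#'   first_latency_ms, truncated)
#' @export
extract_evoked_responses <- function(rec, stims, window_ms = 150,
                                     min_amp_uv = 50, peaks = NULL, ...) {
  stopifnot(inherits(rec, "mea_recording"))
  onsets <- if (is.data.frame(stims)) stims$onset else as.numeric(stims)
  if (length(onsets) && any(diff(onsets) <= 0)) {
    stop("stimulus onsets must be strictly increasing")
  }
  dur <- recording_duration(rec)
  if (length(onsets) && (min(onsets) < rec$t0 || max(onsets) > rec$t0 + dur)) {
    stop("stimulus onsets fall outside the recording")
  }
  if (is.null(peaks)) peaks <- detect_peaks_frame(rec, ...)
  w <- window_ms / 1000
  ap_rows <- vector("list", length(onsets))
  stim_rows <- vector("list", length(onsets))
  for (i in seq_along(onsets)) {
    on <- onsets[i]
    w_end <- on + w
    truncated <- FALSE
    if (i < length(onsets) && w_end > onsets[i + 1L]) {
      w_end <- onsets[i + 1L]
      truncated <- TRUE
    }
    sel <- peaks$t > on & peaks$t <= w_end & abs(peaks$amp_uv) > min_amp_uv
    hits <- peaks[sel, , drop = FALSE]
    hits <- hits[order(hits$t), , drop = FALSE]
    if (nrow(hits)) {
      ap_rows[[i]] <- data.frame(stim_index = i, channel = hits$channel,
                                 t = hits$t,
                                 latency_ms = (hits$t - on) * 1000,
                                 amp_uv = hits$amp_uv)
    }
    stim_rows[[i]] <- data.frame(
      stim_index = i, onset = on, n_aps = nrow(hits),
      first_latency_ms = if (nrow(hits)) (hits$t[1L] - on) * 1000 else NA_real_,
      truncated = truncated)
  }
  aps <- do.call(rbind, ap_rows)
  if (is.null(aps)) {
    aps <- data.frame(stim_index = integer(0), channel = character(0),
                      t = numeric(0), latency_ms = numeric(0),
                      amp_uv = numeric(0))
  }
  list(aps = aps, stims = do.call(rbind, stim_rows) %||%
         data.frame(stim_index = integer(0), onset = numeric(0),
                    n_aps = integer(0), first_latency_ms = numeric(0),
                    truncated = logical(0)))
}

#' Latency and delta-latency statistics of evoked responses
#'
#' First-AP latency is the time from stimulus onset to the first accepted AP
#' peak; delta latencies are the delays between the peaks of consecutive APs
#' within one response. Summaries (mean, SD, 95% CI, n) are computed per
#' group when grouping metadata is supplied.
#'
#' @param responses output of [extract_evoked_responses()]
#' @param groups optional vector (one entry per stimulus, e.g. frequency or
#'   intensity labels) to group by; default a single group
#' @return list: `latency` (per-group first-AP latency summary, ms),
#'   `delta` (per-group delta-latency summary, ms), `aps_per_pulse`
#'   (per-group table of AP counts per stimulus)
#' @export
latency_stats <- function(responses, groups = NULL) {
  st <- responses$stims
  if (is.null(groups)) groups <- rep("all", nrow(st))
  stopifnot(length(groups) == nrow(st))
  st$group <- as.character(groups)
  ap <- responses$aps
  ap$group <- st$group[match(ap$stim_index, st$stim_index)]

  summarise <- function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n == 0L) {
      return(data.frame(n = 0L, mean = NA_real_, sd = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_))
    }
    m <- mean(x)
    s <- if (n > 1L) sd(x) else NA_real_
    half <- if (n > 1L) qt(0.975, n - 1L) * s / sqrt(n) else NA_real_
    data.frame(n = n, mean = m, sd = s, ci_lo = m - half, ci_hi = m + half)
  }

  lat <- do.call(rbind, lapply(split(st$first_latency_ms, st$group), summarise))
  lat <- cbind(group = rownames(lat), lat)
  rownames(lat) <- NULL

  deltas <- do.call(rbind, lapply(split(ap, list(ap$group, ap$stim_index),
                                        drop = TRUE), function(g) {
    if (nrow(g) < 2L) return(NULL)
    data.frame(group = g$group[1L], delta_ms = diff(sort(g$t)) * 1000)
  }))
  if (is.null(deltas)) {
    delta <- data.frame(group = character(0), n = integer(0),
                        mean = numeric(0), sd = numeric(0),
                        ci_lo = numeric(0), ci_hi = numeric(0))
  } else {
    delta <- do.call(rbind, lapply(split(deltas$delta_ms, deltas$group),
                                   summarise))
    delta <- cbind(group = rownames(delta), delta)
    rownames(delta) <- NULL
  }

  app <- as.data.frame(table(group = st$group, n_aps = st$n_aps),
                       stringsAsFactors = FALSE)
  app <- app[app$Freq > 0, ]
  rownames(app) <- NULL
  list(latency = lat, delta = delta, aps_per_pulse = app)
}

#' Stimulation efficacy by neuron count
#'
#' Summarises firing rates of stimulated circuits against their baseline
#' epochs per neuron count: median rates per condition and the fold-change
#' of the stimulated over the baseline median. No hypothesis testing is
#' performed; the table is meant for export.
#'
#' @param rates data.frame with columns `circuit`, `n_neurons`, `condition`
#'   (must include `"baseline"` and `"stim"`), `rate_hz`
#' @return data.frame: `n_neurons`, `median_baseline_hz`, `median_stim_hz`,
#'   `fold_change`, `n_circuits`
#' @export
stim_efficacy_by_count <- function(rates) {
  stopifnot(all(c("circuit", "n_neurons", "condition", "rate_hz") %in%
                  names(rates)))
  if (!"baseline" %in% rates$condition) stop("missing baseline epoch")
  out <- do.call(rbind, lapply(split(rates, rates$n_neurons), function(g) {
    base <- g$rate_hz[g$condition == "baseline"]
    stim <- g$rate_hz[g$condition == "stim"]
    if (!length(base)) stop("missing baseline epoch for n = ", g$n_neurons[1L])
    data.frame(n_neurons = g$n_neurons[1L],
               median_baseline_hz = median(base),
               median_stim_hz = if (length(stim)) median(stim) else NA_real_,
               fold_change = if (length(stim)) median(stim) / median(base)
                             else NA_real_,
               n_circuits = length(unique(g$circuit)))
  }))
  rownames(out) <- NULL
  out[order(out$n_neurons), ]
}
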