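#' Baseline-SD threshold-crossing time of an AP on one trace
#'
#' Implements the conduction-velocity reference-point rule: the baseline
#' mean and SD are computed on the `window_ms` span immediately preceding
#' `seed_time` (an estimate placed up to ~1 ms before the AP onset), and the
#' crossing is the first sample after `seed_time` whose deviation from the
#' baseline mean exceeds `k_sd` baseline SDs. If a detected spike lies
#' inside the baseline window the AP is rejected (`rejected_contaminated`)
#' because the SD estimate would be distorted; if no crossing occurs within
#' `search_ms` the AP is rejected (`rejected_no_crossing`).
#'
#' @param trace numeric vector of preprocessed samples (uV)
#' @param fs sampling rate (Hz)
#' @param seed_time seed time (s), roughly 1 ms before the AP onset
#' @param t0 trace start time (s)
#' @param window_ms baseline window length (ms); 10 ms throughout
#' @param k_sd threshold in baseline SDs; 5 throughout
#' @param search_ms search horizon after the seed (ms)
#' @param spike_times detected spike times (s) on this trace, used for the
#'   baseline-contamination check (NULL skips the check)
#' @param polarity crossing criterion: `"mag"` (|deviation| from baseline
#'   mean; default, appropriate for negative-going extracellular APs),
#'   `"neg"`, or `"pos"`
#' @param interpolate refine the crossing to sub-sample precision by linear
#'   interpolation between the last sub-threshold and first supra-threshold
#'   samples (default); `FALSE` returns the first supra-threshold sample
#'   time itself. Interpolation leaves on-grid crossings unchanged and
#'   removes the sample-quantisation bias from velocity estimates
#' @return list: `status` (`"accepted"`, `"rejected_contaminated"`,
#'   `"rejected_no_crossing"`), `t_cross` (s or NA), `baseline_mean`,
#'   `baseline_sd`
#' @export
threshold_crossing_time <- function(trace, fs, seed_time, t0 = 0,
                                    window_ms = 10, k_sd = 5, search_ms = 5,
                                    spike_times = NULL,
                                    polarity = c("mag", "neg", "pos"),
                                    interpolate = TRUE) {
  polarity <- match.arg(polarity)
  win <- window_ms / 1000
  if (seed_time - win < t0 - 1e-12) {
    stop("seed_time minus the baseline window precedes the trace start")
  }
  reject <- function(status) list(status = status, t_cross = NA_real_,
                                  baseline_mean = NA_real_,
                                  baseline_sd = NA_real_)
  if (!is.null(spike_times) &&
      any(spike_times >= seed_time - win & spike_times < seed_time)) {
    return(reject("rejected_contaminated"))
  }
  i_seed <- time_to_sample(seed_time, fs, t0)
  i_lo <- time_to_sample(seed_time - win, fs, t0)
  i_hi <- i_seed - 1L
  if (i_hi <= i_lo) stop("baseline window contains too few samples")
  base <- trace[i_lo:i_hi]
  m <- mean(base)
  s <- sd(base)
  i_end <- min(length(trace), time_to_sample(seed_time + search_ms / 1000, fs, t0))
  if (i_seed > length(trace)) return(reject("rejected_no_crossing"))
  seg <- trace[i_seed:i_end]
  dev <- switch(polarity,
                mag = abs(seg - m),
                neg = m - seg,
                pos = seg - m)
  thr <- k_sd * s
  hit <- which(dev > thr)
  if (!length(hit)) return(reject("rejected_no_crossing"))
  t_cross <- sample_to_time(i_seed + hit[1L] - 1L, fs, t0)
  if (interpolate && hit[1L] > 1L) {
    d0 <- dev[hit[1L] - 1L]
    d1 <- dev[hit[1L]]
    if (d1 > d0) {
      frac <- (thr - d0) / (d1 - d0)  # in (0, 1]; 1 when exactly on-grid
      t_cross <- t_cross - (1 - frac) / fs
    }
  }
  list(status = "accepted", t_cross = t_cross,
       baseline_mean = m, baseline_sd = s)
}

#' Pairwise conduction velocities from per-electrode crossing times
#'
#' For each pair of consecutive accepted electrodes along the path (and,
#' optionally, the end-to-end pair of the first and last accepted
#' electrodes) the velocity is the path distance divided by the crossing
#' time difference. Non-positive time differences are below the time
#' resolution and rejected as non-physical.
#'
#' @param crossings data.frame with one row per path electrode in path
#'   order: `channel`, `cum_um` (cumulative path distance), `status`,
#'   `t_cross`
#' @param ap_id identifier carried into the output
#' @param end_to_end also emit the first-to-last accepted pair
#' @return data.frame of velocity estimates: `ap_id`, `channel_a`,
#'   `channel_b`, `t_a`, `t_b`, `distance_um`, `velocity` (m/s),
#'   `pair_type`, `status`
#' @export
ap_velocity <- function(crossings, ap_id = 1L, end_to_end = TRUE) {
  acc <- crossings[crossings$status == "accepted", , drop = FALSE]
  empty <- data.frame(ap_id = integer(0), channel_a = character(0),
                      channel_b = character(0), t_a = numeric(0),
                      t_b = numeric(0), distance_um = numeric(0),
                      velocity = numeric(0), pair_type = character(0),
                      status = character(0))
  if (nrow(acc) < 2L) return(empty)
  pair_rows <- function(i, j, type) {
    dt <- acc$t_cross[j] - acc$t_cross[i]
    d <- acc$cum_um[j] - acc$cum_um[i]
    ok <- dt > 0
    data.frame(ap_id = ap_id, channel_a = acc$channel[i],
               channel_b = acc$channel[j],
               t_a = acc$t_cross[i], t_b = acc$t_cross[j],
               distance_um = d,
               velocity = ifelse(ok, d * 1e-6 / dt, NA_real_),
               pair_type = type,
               status = ifelse(ok, "accepted", "rejected_nonpositive_dt"))
  }
  out <- pair_rows(seq_len(nrow(acc) - 1L), seq_len(nrow(acc) - 1L) + 1L,
                   "consecutive")
  if (end_to_end && nrow(acc) > 2L) {
    out <- rbind(out, pair_rows(1L, nrow(acc), "end_to_end"))
  }
  rownames(out) <- NULL
  out
}

#' Estimate conduction velocities along a layout path
#'
#' Automates the full velocity procedure on a preprocessed recording: seed
#' times are taken 1 ms before each detected spike on the first path
#' electrode (or supplied manually), the 5-SD threshold crossing is located
#' on every path electrode (baseline 10 ms window, contamination rejection
#' against that electrode's detected spikes), and pairwise velocities are
#' computed along the known geometry. The per-electrode search horizon is
#' widened by the propagation delay a slow AP (velocity prior lower bound)
#' would need to reach that electrode, so downstream crossings of the same
#' AP are not missed and later bursts are not mismatched.
#'
#' @param rec preprocessed `mea_recording` whose channels include the path
#' @param layout an `mea_layout`
#' @param path_id which layout path to analyse
#' @param spikes optional detected `mea_spiketrains` (defaults to
#'   [detect_spikes()] on `rec`)
#' @param seed_times optional manual seed times (s); default: automatic
#'   seeds from first-electrode spikes
#' @param seed_offset_ms seed placement before the detected peak (ms)
#' @param window_ms,k_sd,search_ms,polarity,interpolate passed to
#'   [threshold_crossing_time()]
#' @param v_prior velocity prior `c(min, max)` (m/s) bounding expected
#'   propagation delays
#' @param end_to_end also emit end-to-end pairs
#' @return data.frame of velocity estimates with a `segment` column (NA when
#'   the layout has no segments); rejected APs appear with their rejection
#'   status and NA velocity
#' @export
estimate_velocities <- function(rec, layout, path_id = 1, spikes = NULL,
                                seed_times = NULL, seed_offset_ms = 1,
                                window_ms = 10, k_sd = 5, search_ms = 5,
                                polarity = "mag", interpolate = TRUE,
                                v_prior = c(0.1, 10), end_to_end = TRUE) {
  stopifnot(inherits(rec, "mea_recording"), inherits(layout, "mea_layout"))
  path <- layout$paths[[path_id]]
  if (!all(path %in% rec$channel_ids)) {
    stop("recording lacks path channels: ",
         paste(setdiff(path, rec$channel_ids), collapse = ", "))
  }
  cum <- path_cumdist(layout, path)
  if (is.null(spikes)) spikes <- detect_spikes(rec)
  if (is.null(seed_times)) {
    seed_times <- spikes$trains[[path[1L]]] - seed_offset_ms / 1000 + rec$t0
  }
  seed_times <- seed_times[seed_times - window_ms / 1000 >= rec$t0]
  if (!length(seed_times)) {
    out <- ap_velocity(data.frame(channel = character(0), cum_um = numeric(0),
                                  status = character(0), t_cross = numeric(0)))
    out$segment <- character(0)
    return(out)
  }
  seg_tab <- if (!is.null(layout$segments)) layout$segments[[path_id]] else NULL
  res <- vector("list", length(seed_times))
  for (a in seq_along(seed_times)) {
    st <- seed_times[a]
    crossings <- data.frame(channel = path, cum_um = cum,
                            status = NA_character_, t_cross = NA_real_)
    contaminated <- FALSE
    for (j in seq_along(path)) {
      extra_ms <- cum[j] * 1e-6 / v_prior[1L] * 1000
      cr <- threshold_crossing_time(
        rec$data[match(path[j], rec$channel_ids), ], rec$fs,
        seed_time = st, t0 = rec$t0, window_ms = window_ms, k_sd = k_sd,
        search_ms = search_ms + extra_ms,
        spike_times = spikes$trains[[path[j]]] + rec$t0,
        polarity = polarity, interpolate = interpolate)
      crossings$status[j] <- cr$status
      crossings$t_cross[j] <- cr$t_cross
      if (cr$status == "rejected_contaminated") contaminated <- TRUE
    }
    if (contaminated) {
      # a distorted baseline anywhere invalidates the whole AP measurement
      res[[a]] <- data.frame(ap_id = a, channel_a = path[1L],
                             channel_b = path[length(path)],
                             t_a = st, t_b = NA_real_,
                             distance_um = cum[length(cum)],
                             velocity = NA_real_, pair_type = "path",
                             status = "rejected_contaminated")
    } else {
      est <- ap_velocity(crossings, ap_id = a, end_to_end = end_to_end)
      if (nrow(est) == 0L) {
        est <- data.frame(ap_id = a, channel_a = path[1L],
                          channel_b = path[length(path)],
                          t_a = st, t_b = NA_real_,
                          distance_um = cum[length(cum)],
                          velocity = NA_real_, pair_type = "path",
                          status = "rejected_no_crossing")
      }
      res[[a]] <- est
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$segment <- NA_character_
  if (!is.null(seg_tab)) {
    mid <- (out$distance_um / 2) +
      cum[match(out$channel_a, path)]
    out$segment <- segment_at(seg_tab, mid)
  }
  out
}

#' Per-segment conduction-velocity summary
#'
#' Groups accepted consecutive-pair velocity estimates by segment label and
#' summarises each group (median, interquartile range, counts). A summary
#' statistic is only emitted for groups with at least `min_aps` distinct
#' accepted APs; smaller groups are reported with counts but NA statistics.
#'
#' @param estimates output of [estimate_velocities()]
#' @param min_aps minimum distinct accepted APs per group (default 10)
#' @return data.frame: `segment`, `n_estimates`, `n_aps`, `median`, `q25`,
#'   `q75` (velocities in m/s)
#' @export
velocity_by_segment <- function(estimates, min_aps = 10) {
  acc <- estimates[estimates$status == "accepted" &
                     estimates$pair_type == "consecutive", , drop = FALSE]
  if (nrow(acc) == 0L) {
    return(data.frame(segment = character(0), n_estimates = integer(0),
                      n_aps = integer(0), median = numeric(0),
                      q25 = numeric(0), q75 = numeric(0)))
  }
  seg <- acc$segment
  seg[is.na(seg)] <- "(all)"
  groups <- split(acc, seg)
  out <- do.call(rbind, Map(function(lab, g) {
    n_aps <- length(unique(g$ap_id))
    enough <- n_aps >= min_aps
    data.frame(segment = lab,
               n_estimates = nrow(g), n_aps = n_aps,
               median = if (enough) median(g$velocity) else NA_real_,
               q25 = if (enough) unname(quantile(g$velocity, 0.25)) else NA_real_,
               q75 = if (enough) unname(quantile(g$velocity, 0.75)) else NA_real_)
  }, names(groups), groups))
  rownames(out) <- NULL
  out
}
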