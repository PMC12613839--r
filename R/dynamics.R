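#' Interspike-interval histogram of one spike train
#'
#' Bins consecutive-spike intervals at 1 ms by default; intervals beyond
#' `max_isi_ms` are pooled into an overflow bin (still counted in `n_isi`).
#'
#' @param train sorted spike times (s)
#' @param bin_ms bin width (ms)
#' @param max_isi_ms histogram range cap (ms)
#' @return object of class `isi_histogram`: `bin_edges` (ms; the last bin is
#'   the overflow bin), `counts`, `n_isi`
#' @export
isi_histogram <- function(train, bin_ms = 1, max_isi_ms = 1000) {
  n_bins <- as.integer(ceiling(max_isi_ms / bin_ms))
  edges <- c(seq(0, n_bins * bin_ms, by = bin_ms), Inf)
  if (length(train) < 2L) {
    counts <- integer(n_bins + 1L)
  } else {
    isi_ms <- diff(sort(train)) * 1000
    # guard against float error pushing an on-boundary interval down a bin
    bin <- pmin(floor(isi_ms / bin_ms + 1e-9) + 1L, n_bins + 1L)
    counts <- tabulate(bin, nbins = n_bins + 1L)
  }
  structure(list(bin_edges = edges, counts = counts, n_isi = sum(counts),
                 bin_ms = bin_ms, max_isi_ms = max_isi_ms),
            class = "isi_histogram")
}

#' Kullback-Leibler divergence between two ISI histograms
#'
#' `KL(P, Q) = sum_x P(x) log(P(x) / Q(x))` in nats, after normalising the
#' counts to probabilities. Empty bins are handled by additive smoothing:
#' `epsilon` is added to every bin of both probability vectors, which are
#' then renormalised. The default `epsilon = "auto"` uses
#' `1 / (n_isi_P + n_isi_Q)`; `epsilon = 0` evaluates the formula exactly
#' (bins where P = 0 contribute 0; P > 0 with Q = 0 yields Inf).
#'
#' @param P,Q `isi_histogram` objects on the same binning
#' @param epsilon per-bin additive smoothing, or `"auto"`
#' @return divergence in nats (>= 0)
#' @export
kl_divergence <- function(P, Q, epsilon = "auto") {
  stopifnot(inherits(P, "isi_histogram"), inherits(Q, "isi_histogram"))
  if (P$bin_ms != Q$bin_ms || length(P$counts) != length(Q$counts)) {
    stop("histograms use incompatible binnings")
  }
  if (P$n_isi == 0L || Q$n_isi == 0L) stop("both histograms must be non-empty")
  if (identical(epsilon, "auto")) epsilon <- 1 / (P$n_isi + Q$n_isi)
  p <- P$counts / P$n_isi
  q <- Q$counts / Q$n_isi
  if (epsilon > 0) {
    p <- (p + epsilon) / (1 + length(p) * epsilon)
    q <- (q + epsilon) / (1 + length(q) * epsilon)
  }
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

#' Per-electrode ISI divergence between two conditions
#'
#' Computes `KL(baseline, treated)` of the ISI histograms of every electrode
#' in a condition pair. To avoid artifacts from sparse histograms,
#' electrodes where either condition has `min_isi` or fewer intervals are
#' excluded and reported as skipped (default: more than 400 ISI values are
#' required).
#'
#' @param pair an [condition_pair()]
#' @param min_isi exclusion threshold: electrodes with `n_isi <= min_isi`
#'   in either condition are skipped
#' @param bin_ms,max_isi_ms histogram parameters
#' @param epsilon passed to [kl_divergence()]
#' @return data.frame: `channel`, `n_isi_baseline`, `n_isi_treated`,
#'   `included`, `kl` (NA for skipped electrodes); warns if every electrode
#'   is excluded
#' @export
condition_divergence <- function(pair, min_isi = 400, bin_ms = 1,
                                 max_isi_ms = 1000, epsilon = "auto") {
  stopifnot(inherits(pair, "mea_condition_pair"))
  ids <- pair$baseline$channel_ids
  out <- data.frame(channel = ids,
                    n_isi_baseline = NA_integer_,
                    n_isi_treated = NA_integer_,
                    included = FALSE, kl = NA_real_)
  for (i in seq_along(ids)) {
    hb <- isi_histogram(pair$baseline$trains[[ids[i]]], bin_ms, max_isi_ms)
    ht <- isi_histogram(pair$treated$trains[[ids[i]]], bin_ms, max_isi_ms)
    out$n_isi_baseline[i] <- hb$n_isi
    out$n_isi_treated[i] <- ht$n_isi
    if (hb$n_isi > min_isi && ht$n_isi > min_isi) {
      out$included[i] <- TRUE
      out$kl[i] <- kl_divergence(hb, ht, epsilon = epsilon)
    }
  }
  if (!any(out$included)) {
    warning("all electrodes excluded by the >", min_isi, " ISI filter")
  }
  out
}

#' Spike-contrast synchrony of a set of spike trains
#'
#' Multi-timescale synchrony measure: over a geometric grid of bin sizes
#' from half the recording span down to the minimum ISI, spikes of all
#' trains are pooled into half-overlapping bins; the synchrony curve is the
#' product of a contrast term (how strongly the pooled histogram alternates,
#' `sum |diff(theta)| / (2 * n_spikes)`) and an active-train term (the
#' spike-weighted mean fraction of trains active per occupied bin, scaled to
#' `[0, 1]`). The returned synchrony is the curve maximum: 1 for identical
#' trains, near 0 for independent ones.
#'
#' @param trains an `mea_spiketrains` (or plain list of spike-time vectors)
#'   with at least two non-empty trains
#' @param t_start,t_stop analysis span (s); default full recording
#' @param shrink geometric bin-size shrink factor per grid step
#' @param min_bin floor of the bin-size grid (s); the smallest bin used is
#'   `max(min_isi / 2, min_bin)`. The 10 ms default follows the algorithm's
#'   reference implementation and keeps the cost bounded for long sparse
#'   recordings
#' @param return_curve also return the per-bin-size synchrony curve
#' @return synchrony value in (0, 1]; with `return_curve = TRUE`, a list
#'   with `synchrony` and a data.frame `curve` (bin_size, contrast,
#'   active_st, synchrony)
#' @export
spike_contrast <- function(trains, t_start = 0, t_stop = NULL, shrink = 0.9,
                           min_bin = 0.01, return_curve = FALSE) {
  if (inherits(trains, "mea_spiketrains")) {
    if (is.null(t_stop)) t_stop <- trains$duration
    trains <- trains$trains
  }
  trains <- trains[lengths(trains) > 0L]
  n_tr <- length(trains)
  if (n_tr < 2L) stop("spike contrast needs >= 2 non-empty trains")
  if (is.null(t_stop)) t_stop <- max(unlist(trains))
  dur <- t_stop - t_start
  stopifnot(dur > 0)
  isi <- unlist(lapply(trains, function(x) if (length(x) > 1L) diff(x)))
  isi_min <- if (length(isi)) min(isi) else dur
  bin_min <- max(isi_min / 2, min_bin)
  bin_max <- dur / 2
  n_steps <- max(1L, ceiling(log(bin_min / bin_max) / log(shrink)))
  bin_sizes <- bin_max * shrink^(seq_len(n_steps) - 1L)
  n_spikes <- sum(lengths(trains))

  curve <- data.frame(bin_size = bin_sizes, contrast = NA_real_,
                      active_st = NA_real_, synchrony = NA_real_)
  for (b in seq_along(bin_sizes)) {
    step <- bin_sizes[b] / 2
    edges <- seq(t_start, t_stop + step, by = step)
    if (length(edges) < 3L) edges <- c(t_start, t_start + step, t_stop + step)
    nb <- length(edges) - 1L
    theta <- 0
    n_act <- 0
    for (tr in trains) {
      tr2 <- tr[tr >= t_start & tr <= t_stop]
      h <- tabulate(pmin(findInterval(tr2, edges), nb), nbins = nb)
      ov <- h[-length(h)] + h[-1L]  # half-overlapping bins of width bin_size
      theta <- theta + ov
      n_act <- n_act + (ov > 0)
    }
    active_st <- (sum(n_act * theta) / sum(theta) - 1) / (n_tr - 1)
    contrast <- sum(abs(diff(theta))) / (2 * n_spikes)
    curve$contrast[b] <- contrast
    curve$active_st[b] <- active_st
    curve$synchrony[b] <- contrast * active_st
  }
  s <- max(curve$synchrony)
  if (return_curve) list(synchrony = s, curve = curve) else s
}

#' Participation ratio of binned circuit activity
#'
#' Bins every spike train into counts (5 ms bins by default), forms the
#' pairwise Pearson correlation matrix, and returns
#' `PR = (sum lambda_i)^2 / (N * sum lambda_i^2)` over its eigenvalues: an
#' eigenvalue-based dimensionality in (0, 1]. Decoupled activity gives
#' PR near 1; fully coupled (rank-1) activity gives exactly 1/N. Trains
#' with zero variance after binning cannot enter a correlation matrix and
#' are dropped from N with a warning.
#'
#' @param trains an `mea_spiketrains` (or list of spike-time vectors plus
#'   `duration`)
#' @param bin_ms bin width (ms)
#' @param duration recording length (s); taken from the spike-train set if
#'   not given
#' @return participation ratio in (0, 1]
#' @export
participation_ratio <- function(trains, bin_ms = 5, duration = NULL) {
  if (inherits(trains, "mea_spiketrains")) {
    if (is.null(duration)) duration <- trains$duration
    trains <- trains$trains
  }
  stopifnot(!is.null(duration), duration > 0)
  counts <- bin_spike_counts(trains, bin_ms, duration)
  keep <- apply(counts, 2L, function(x) stats::var(x) > 0)
  if (!any(keep)) stop("all trains are empty or constant after binning")
  if (any(!keep)) {
    warning(sum(!keep), " zero-variance train(s) dropped from N")
    counts <- counts[, keep, drop = FALSE]
  }
  n <- ncol(counts)
  if (n == 1L) return(1)
  lambda <- eigen(cor(counts), symmetric = TRUE, only.values = TRUE)$values
  sum(lambda)^2 / (n * sum(lambda^2))
}

# Bin spike trains to a (bins x trains) count matrix.
bin_spike_counts <- function(trains, bin_ms, duration) {
  n_bins <- max(1L, as.integer(ceiling(duration * 1000 / bin_ms)))
  sapply(trains, function(tr) {
    idx <- pmin(floor(tr * 1000 / bin_ms) + 1L, n_bins)
    tabulate(idx, nbins = n_bins)
  })
}

#' MaxInterval burst detection on one spike train
#'
#' Rule-based burst finder. Candidate bursts are maximal runs of spikes
#' whose consecutive ISIs are all at most `max_isi_ms`; candidates separated
#' by less than `min_ibi_ms` are merged (any lone spikes falling inside the
#' merged span are absorbed); merged candidates failing `min_spikes` or
#' `min_duration_ms` are discarded. Default parameters: minimum interburst
#' interval 200 ms, minimum burst duration 1 ms, minimum 3 spikes per burst,
#' maximum in-burst ISI 10 ms.
#'
#' @param train sorted spike times (s)
#' @param max_isi_ms maximum ISI inside a burst (ms)
#' @param min_spikes minimum spikes per burst
#' @param min_duration_ms minimum burst duration (ms)
#' @param min_ibi_ms minimum interburst interval (ms); closer bursts merge
#' @return data.frame: `start`, `end` (s), `n_spikes`, `duration_s`
#' @export
detect_bursts <- function(train, max_isi_ms = 10, min_spikes = 3,
                          min_duration_ms = 1, min_ibi_ms = 200) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0), duration_s = numeric(0))
  n <- length(train)
  if (n < 2L) return(empty)
  train <- sort(train)
  max_isi <- max_isi_ms / 1000
  min_ibi <- min_ibi_ms / 1000
  # maximal runs with consecutive ISIs <= max_isi; candidates need >= 2 spikes
  brk <- which(diff(train) > max_isi)
  starts_i <- c(1L, brk + 1L)
  ends_i <- c(brk, n)
  cand <- which(ends_i > starts_i)
  if (!length(cand)) return(empty)
  s_i <- starts_i[cand]
  e_i <- ends_i[cand]
  # merge candidates whose gap is below the minimum interburst interval
  ms <- s_i[1L]
  me <- e_i[1L]
  merged <- list()
  for (k in seq_along(s_i)[-1L]) {
    if (train[s_i[k]] - train[me] < min_ibi) {
      me <- e_i[k]
    } else {
      merged[[length(merged) + 1L]] <- c(ms, me)
      ms <- s_i[k]
      me <- e_i[k]
    }
  }
  merged[[length(merged) + 1L]] <- c(ms, me)
  rows <- lapply(merged, function(se) {
    # absorb every spike inside the merged span
    n_sp <- se[2L] - se[1L] + 1L
    dur <- train[se[2L]] - train[se[1L]]
    if (n_sp >= min_spikes && dur >= min_duration_ms / 1000) {
      data.frame(start = train[se[1L]], end = train[se[2L]],
                 n_spikes = n_sp, duration_s = dur)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Network bursts across the electrodes of a circuit
#'
#' A network burst is accepted where every active electrode (by default,
#' every electrode with at least one burst; optionally the strict full
#' electrode set) has a burst onset within a common `window_ms` span. The
#' event time is the earliest onset of the group; onsets consumed by an
#' event are not reused.
#'
#' @param bursts named list of per-electrode burst tables from
#'   [detect_bursts()] (identical parameters)
#' @param window_ms coincidence window (ms)
#' @param electrodes `"active"` (electrodes with >= 1 burst; a recording
#'   with no bursts anywhere then has no network bursts) or a character
#'   vector naming the required electrode set (electrodes without bursts
#'   then make network bursts impossible)
#' @return data.frame: `t` (event time, s), `n_electrodes`, `span_ms`
#' @export
detect_network_bursts <- function(bursts, window_ms = 5,
                                  electrodes = "active") {
  empty <- data.frame(t = numeric(0), n_electrodes = integer(0),
                      span_ms = numeric(0))
  if (identical(electrodes, "active")) {
    req <- names(bursts)[vapply(bursts, nrow, integer(1)) > 0L]
    if (length(req) == 0L) return(empty)  # no bursts anywhere
  } else {
    req <- electrodes
    if (length(req) == 0L) stop("empty electrode set")
  }
  if (any(!req %in% names(bursts)) ||
      any(vapply(bursts[req], nrow, integer(1)) == 0L)) {
    return(empty)  # some required electrode never bursts
  }
  w <- window_ms / 1000
  onset <- data.frame(
    t = unlist(lapply(bursts[req], function(b) b$start), use.names = FALSE),
    el = rep(req, vapply(bursts[req], nrow, integer(1))))
  onset <- onset[order(onset$t), ]
  events <- list()
  i <- 1L
  while (i <= nrow(onset)) {
    in_win <- onset$t >= onset$t[i] & onset$t <= onset$t[i] + w
    if (all(req %in% onset$el[in_win])) {
      events[[length(events) + 1L]] <- data.frame(
        t = onset$t[i], n_electrodes = length(req),
        span_ms = (max(onset$t[in_win]) - onset$t[i]) * 1000)
      i <- max(which(in_win)) + 1L  # consume the window
    } else {
      i <- i + 1L
    }
  }
  out <- do.call(rbind, events)
  if (is.null(out)) empty else out
}

#' Mean firing rate of a spike train
#' @param train spike times (s)
#' @param duration recording length (s), > 0
#' @return rate in Hz
#' @export
firing_rate <- function(train, duration) {
  if (duration <= 0) stop("`duration` must be > 0")
  length(train) / duration
}

#' Cross-correlogram directionality between two spike trains
#'
#' Bins both trains (1 ms default) and computes the cross-correlogram
#' `cc(l) = sum_t a(t) * b(t + l)` for lags up to `max_lag_ms`. A positive
#' peak lag means `train_b` follows `train_a`. The asymmetry index is
#' (area at positive lags - area at negative lags) / total area.
#'
#' @param train_a,train_b spike times (s), both non-empty
#' @param duration recording length (s)
#' @param max_lag_ms maximum lag (ms)
#' @param bin_ms bin width (ms)
#' @return list: `peak_lag_ms`, `asymmetry`, `lags_ms`, `cc`
#' @export
directionality <- function(train_a, train_b, duration, max_lag_ms = 50,
                           bin_ms = 1) {
  if (!length(train_a) || !length(train_b)) stop("both trains must be non-empty")
  a <- bin_spike_counts(list(train_a), bin_ms, duration)[, 1L]
  b <- bin_spike_counts(list(train_b), bin_ms, duration)[, 1L]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("degenerate (constant) binned trains")
  }
  n_lag <- as.integer(round(max_lag_ms / bin_ms))
  lags <- (-n_lag):n_lag
  n <- length(a)
  cc <- vapply(lags, function(l) {
    if (l >= 0) sum(a[seq_len(n - l)] * b[seq_len(n - l) + l])
    else sum(a[seq_len(n + l) - l] * b[seq_len(n + l)])
  }, numeric(1))
  total <- sum(cc)
  asym <- if (total > 0) (sum(cc[lags > 0]) - sum(cc[lags < 0])) / total else 0
  peak <- lags[which.max(cc)] * bin_ms
  list(peak_lag_ms = peak, asymmetry = asym, lags_ms = lags * bin_ms, cc = cc)
}

#' One-row synchrony summary of a circuit
#'
#' Bundles the per-circuit dynamics metrics: spike contrast, participation
#' ratio, burst and network-burst rates, and the mean per-electrode firing
#' rate.
#'
#' @param trains an `mea_spiketrains`
#' @param bin_ms_pr participation-ratio bin width (ms)
#' @param burst_params named list overriding [detect_bursts()] defaults
#' @param nb_window_ms network-burst coincidence window (ms)
#' @return one-row data.frame: `spike_contrast`, `participation_ratio`,
#'   `burst_rate_per_min`, `network_burst_rate_per_min`, `mean_rate_hz`,
#'   `n_trains`
#' @export
synchrony_summary <- function(trains, bin_ms_pr = 5, burst_params = list(),
                              nb_window_ms = 5) {
  stopifnot(inherits(trains, "mea_spiketrains"))
  dur <- trains$duration
  bursts <- lapply(trains$trains, function(tr) {
    do.call(detect_bursts, c(list(train = tr), burst_params))
  })
  nb <- detect_network_bursts(bursts, window_ms = nb_window_ms)
  n_bursts <- sum(vapply(bursts, nrow, integer(1)))
  sc <- tryCatch(spike_contrast(trains), error = function(e) NA_real_)
  pr <- tryCatch(participation_ratio(trains, bin_ms = bin_ms_pr),
                 error = function(e) NA_real_)
  data.frame(
    spike_contrast = sc,
    participation_ratio = pr,
    burst_rate_per_min = n_bursts / dur * 60,
    network_burst_rate_per_min = nrow(nb) / dur * 60,
    mean_rate_hz = mean(vapply(trains$trains, firing_rate, numeric(1),
                               duration = dur)),
    n_trains = length(trains$trains)
  )
}
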