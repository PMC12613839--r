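# Independent reference implementations used as oracles. These are written
# as literal, loop-based transcriptions of the published definitions and are
# deliberately kept free of the vectorised tricks the package uses, so that
# agreement is a genuine cross-check of the computation.

# Spike-contrast, naive: explicit enumeration of half-overlapping bins with
# per-bin interval counting. Shares only the bin-size grid definition with
# the package implementation.
naive_spike_contrast <- function(trains, t_start, t_stop, shrink = 0.9,
                                 min_bin = 0.01) {
  trains <- trains[lengths(trains) > 0L]
  n_tr <- length(trains)
  stopifnot(n_tr >= 2L)
  m <- sum(lengths(trains))
  isi <- unlist(lapply(trains, function(x) if (length(x) > 1L) diff(x)))
  isi_min <- if (length(isi)) min(isi) else (t_stop - t_start)
  bin_min <- max(isi_min / 2, min_bin)
  bin_max <- (t_stop - t_start) / 2
  n_steps <- max(1L, ceiling(log(bin_min / bin_max) / log(shrink)))
  bin_sizes <- bin_max * shrink^(seq_len(n_steps) - 1L)

  best <- -Inf
  for (b in bin_sizes) {
    step <- b / 2
    n_bins <- floor((t_stop - t_start) / step)
    theta <- numeric(n_bins)
    n_act <- numeric(n_bins)
    for (k in seq_len(n_bins)) {
      lo <- t_start + (k - 1) * step
      hi <- lo + b
      for (tr in trains) {
        cnt <- sum(tr >= lo & tr < hi)
        theta[k] <- theta[k] + cnt
        if (cnt > 0) n_act[k] <- n_act[k] + 1
      }
    }
    active <- (sum(n_act * theta) / sum(theta) - 1) / (n_tr - 1)
    contrast <- sum(abs(diff(theta))) / (2 * m)
    s <- contrast * active
    if (s > best) best <- s
  }
  best
}

# MaxInterval burst detection, brute force: scan-based run construction,
# iterated pairwise merging until fixed point, then filtering. Same rule
# set, different mechanics.
naive_detect_bursts <- function(train, max_isi_ms = 10, min_spikes = 3,
                                min_duration_ms = 1, min_ibi_ms = 200) {
  train <- sort(train)
  n <- length(train)
  runs <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && (train[j + 1L] - train[j]) <= max_isi_ms / 1000) {
      j <- j + 1L
    }
    if (j > i) runs[[length(runs) + 1L]] <- c(i, j)
    i <- j + 1L
  }
  # merge closest-first until every gap is >= the minimum interburst interval
  repeat {
    if (length(runs) < 2L) break
    merged_any <- FALSE
    for (k in seq_len(length(runs) - 1L)) {
      gap <- train[runs[[k + 1L]][1L]] - train[runs[[k]][2L]]
      if (gap < min_ibi_ms / 1000) {
        runs[[k]] <- c(runs[[k]][1L], runs[[k + 1L]][2L])
        runs[[k + 1L]] <- NULL
        merged_any <- TRUE
        break
      }
    }
    if (!merged_any) break
  }
  keep <- list()
  for (r in runs) {
    n_sp <- r[2L] - r[1L] + 1L
    dur <- train[r[2L]] - train[r[1L]]
    if (n_sp >= min_spikes && dur >= min_duration_ms / 1000) {
      keep[[length(keep) + 1L]] <-
        data.frame(start = train[r[1L]], end = train[r[2L]],
                   n_spikes = n_sp, duration_s = dur)
    }
  }
  if (length(keep)) {
    out <- do.call(rbind, keep)
    rownames(out) <- NULL
    out
  } else {
    data.frame(start = numeric(0), end = numeric(0),
               n_spikes = integer(0), duration_s = numeric(0))
  }
}
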