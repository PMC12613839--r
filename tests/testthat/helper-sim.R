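# Shared fixture builders (all fixtures are generated in code).

# Independent homogeneous Poisson spike trains as an mea_spiketrains.
poisson_train_set <- function(n_trains, rate_hz, duration, seed = NULL) {
  make <- function() {
    trains <- lapply(seq_len(n_trains), function(i) {
      sort(runif(rpois(1L, rate_hz * duration), 0, duration))
    })
    names(trains) <- paste0("ch", seq_len(n_trains))
    spike_train_set(trains, duration = duration)
  }
  if (is.null(seed)) make() else withr::with_seed(seed, make())
}

# A noiseless recording holding hand-placed deflections: `events` is a
# data.frame with channel (index), t (s), amp_uv. Each event is a 0.6 ms
# raised-cosine dip/peak so detection sees a single clean extremum.
synthetic_peak_recording <- function(n_channels, duration, fs = 25000,
                                     events = NULL, noise_sd = 0,
                                     seed = 1) {
  n <- as.integer(duration * fs)
  mat <- if (noise_sd > 0) {
    withr::with_seed(seed, matrix(rnorm(n_channels * n, 0, noise_sd),
                                  nrow = n_channels))
  } else {
    matrix(0, n_channels, n)
  }
  if (!is.null(events)) {
    half <- as.integer(0.0003 * fs)
    for (k in seq_len(nrow(events))) {
      centre <- as.integer(round(events$t[k] * fs)) + 1L
      idx <- (centre - half):(centre + half)
      ok <- idx >= 1L & idx <= n
      shape <- 0.5 * (1 + cos(pi * ((idx - centre) / half)))
      mat[events$channel[k], idx[ok]] <-
        mat[events$channel[k], idx[ok]] + events$amp_uv[k] * shape[ok]
    }
  }
  recording(mat, fs = fs)
}
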