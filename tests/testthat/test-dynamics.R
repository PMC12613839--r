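test_that("ISI histograms bin consecutive intervals at 1 ms", {
  h <- isi_histogram(c(0, 0.010, 0.020, 0.030))
  expect_equal(h$n_isi, 3L)
  expect_equal(h$counts[11], 3L)  # all three 10 ms intervals in [10, 11) ms
  expect_equal(sum(h$counts), h$n_isi)

  expect_equal(isi_histogram(0.5)$n_isi, 0L)
  expect_equal(isi_histogram(numeric(0))$n_isi, 0L)

  # intervals beyond the cap land in the overflow bin but count in n_isi
  h2 <- isi_histogram(c(0, 2.5))
  expect_equal(h2$n_isi, 1L)
  expect_equal(h2$counts[length(h2$counts)], 1L)
})

test_that("empirical ISI mean of a Poisson train matches 1/rate", {
  tr <- poisson_train_set(1, 10, 1000, seed = 17)$trains[[1]]
  expect_equal(mean(diff(tr)) * 1000, 100, tolerance = 0.05)
})

test_that("KL divergence reproduces hand values and is asymmetric", {
  mk <- function(counts) {
    h <- isi_histogram(numeric(0), bin_ms = 1, max_isi_ms = 2)
    h$counts <- counts
    h$n_isi <- sum(counts)
    h
  }
  P <- mk(c(2, 2, 0))
  Q <- mk(c(1, 3, 0))
  # 0.5 ln 2 + 0.5 ln(2/3) = 0.1438 nats
  expect_equal(kl_divergence(P, Q, epsilon = 0),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
  expect_equal(kl_divergence(Q, P, epsilon = 0),
               0.25 * log(0.5) + 0.75 * log(1.5), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(kl_divergence(P, Q, epsilon = 0),
                                kl_divergence(Q, P, epsilon = 0))))
  # identity, in the epsilon -> 0 limit
  expect_lt(kl_divergence(P, P, epsilon = 1e-12), 1e-10)
})

test_that("KL is non-negative over random histogram pairs, zero iff equal", {
  withr::with_seed(23, {
    for (i in 1:50) {
      nb <- 20
      mk <- function() {
        h <- isi_histogram(numeric(0), bin_ms = 1, max_isi_ms = nb - 1)
        h$counts <- rpois(nb, 3)
        h$n_isi <- sum(h$counts)
        h
      }
      P <- mk()
      Q <- mk()
      if (P$n_isi == 0 || Q$n_isi == 0) next
      expect_gte(kl_divergence(P, Q), 0)
      expect_lt(kl_divergence(P, P), 1e-12)
    }
  })
})

test_that("the >400-ISI exclusion filter drops sparse electrodes", {
  dur <- 100
  t_dense <- seq(0.1, 99, length.out = 600)   # 599 ISIs
  t_sparse <- seq(0.1, 99, length.out = 301)  # 300 ISIs
  base <- spike_train_set(list(a = t_dense, b = t_sparse), dur)
  trt <- spike_train_set(list(a = t_dense + 0.0004, b = t_sparse + 0.0004),
                         dur)
  kl <- condition_divergence(condition_pair(base, trt))
  expect_true(kl$included[kl$channel == "a"])
  expect_false(kl$included[kl$channel == "b"])
  expect_true(is.na(kl$kl[kl$channel == "b"]))

  sparse_only <- spike_train_set(list(b = t_sparse), dur)
  sparse_trt <- spike_train_set(list(b = t_sparse + 1e-4), dur)
  expect_warning(
    condition_divergence(condition_pair(sparse_only, sparse_trt)),
    "excluded")
})

test_that("spike contrast is 1 for identical sparse trains and low for independent", {
  tr <- seq(0.5, 99.5, by = 0.25)
  idn <- spike_train_set(list(a = tr, b = tr, c = tr), 100)
  expect_equal(spike_contrast(idn), 1)

  ind <- poisson_train_set(4, 5, 300, seed = 29)
  s <- spike_contrast(ind)
  expect_lt(s, 0.3)
  expect_gt(s, 0)

  # two trains offset by a lag far beyond every bin size behave like
  # independent trains, not like synchronous ones
  a <- poisson_train_set(1, 5, 40, seed = 30)$trains[[1]]
  lagged <- spike_train_set(list(a = a[a < 20], b = a[a >= 20]), 40)
  expect_lt(spike_contrast(lagged), 0.35)

  one <- spike_train_set(list(a = tr), 100)
  expect_error(spike_contrast(one), ">= 2")
})

test_that("spike contrast agrees with the naive reference implementation", {
  withr::with_seed(31, {
    for (i in 1:8) {
      n <- sample(2:4, 1)
      dur <- runif(1, 4, 8)
      mode <- i %% 3
      trains <- if (mode == 0) {
        lapply(seq_len(n), function(j) sort(runif(rpois(1, 6 * dur), 0, dur)))
      } else if (mode == 1) {
        ev <- sort(runif(rpois(1, 2 * dur), 0, dur))
        lapply(seq_len(n), function(j) {
          sort(pmin(pmax(ev + rnorm(length(ev), 0, 0.005), 0), dur))
        })
      } else {
        base <- sort(runif(40, 0, dur))
        rep(list(base), n)
      }
      names(trains) <- paste0("t", seq_len(n))
      impl <- spike_contrast(spike_train_set(trains, dur))
      ref <- naive_spike_contrast(trains, 0, dur)
      expect_equal(impl, ref, tolerance = 1e-6)
    }
  })
})

test_that("participation ratio hits its analytic anchors", {
  tr <- poisson_train_set(1, 5, 600, seed = 37)$trains[[1]]
  idn <- spike_train_set(list(a = tr, b = tr, c = tr, d = tr), 600)
  # rank-1 correlation: eigenvalues {N, 0, 0, 0} -> PR = 1/N exactly
  expect_equal(participation_ratio(idn), 0.25, tolerance = 1e-12)

  ind <- poisson_train_set(4, 5, 600, seed = 38)
  expect_equal(participation_ratio(ind), 1, tolerance = 0.05)

  one <- poisson_train_set(1, 5, 60, seed = 39)
  expect_equal(participation_ratio(one), 1)

  # zero-variance trains are dropped from N with a warning
  mixed <- spike_train_set(list(a = tr, b = tr, c = numeric(0)), 600)
  expect_warning(pr <- participation_ratio(mixed), "zero-variance")
  expect_equal(pr, 0.5, tolerance = 1e-12)  # two identical trains: 1/2
})

test_that("participation ratio stays in (0, 1] over random circuits", {
  withr::with_seed(41, {
    for (i in 1:25) {
      n <- sample(2:8, 1)
      cfg <- sim_config(n_neurons = n, duration = 60,
                        mean_rate = runif(1, 0.5, 3),
                        burst_rate = runif(1, 0, 1.5),
                        sync_jitter_ms = runif(1, 0, 30),
                        seed = 4100 + i)
      tr <- simulate_spike_trains(cfg)$spikes
      pr <- suppressWarnings(participation_ratio(tr))
      expect_gt(pr, 0)
      expect_lte(pr, 1 + 1e-12)
    }
  })
})

test_that("burst detection applies the MaxInterval rules", {
  b <- detect_bursts(c(0, 0.005, 0.009))
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_spikes, 3L)
  expect_equal(b$duration_s, 0.009)

  # ISIs of 100 ms exceed the 10 ms in-burst maximum
  expect_equal(nrow(detect_bursts(seq(0, 1, by = 0.1))), 0L)

  # two 3-spike runs 150 ms apart merge; 300 ms apart stay separate
  run2 <- function(gap) detect_bursts(c(0, 0.005, 0.009,
                                        gap + c(0, 0.005, 0.009)))
  merged <- run2(0.159)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$n_spikes, 6L)
  expect_equal(nrow(run2(0.309)), 2L)
})

test_that("burst detection equals the brute-force rule enumeration", {
  withr::with_seed(43, {
    for (i in 1:300) {
      n <- sample(2:40, 1)
      # mixture of tight clusters and long gaps to exercise every rule
      gaps <- sample(c(0.002, 0.004, 0.008, 0.012, 0.05, 0.15, 0.25, 0.5),
                     n, replace = TRUE)
      train <- cumsum(gaps)
      a <- detect_bursts(train)
      b <- naive_detect_bursts(train)
      expect_equal(a, b)
    }
  })
})

test_that("network bursts require every active electrode within the window", {
  mk <- function(onsets) {
    data.frame(start = onsets, end = onsets + 0.02,
               n_spikes = rep(3L, length(onsets)),
               duration_s = rep(0.02, length(onsets)))
  }
  hit <- detect_network_bursts(list(e1 = mk(0), e2 = mk(0.002),
                                    e3 = mk(0.004)))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$t, 0)

  miss <- detect_network_bursts(list(e1 = mk(0), e2 = mk(0.002),
                                     e3 = mk(0.008)))
  expect_equal(nrow(miss), 0L)

  # an electrode without bursts blocks network bursts under the strict set
  none <- detect_network_bursts(list(e1 = mk(0), e2 = mk(0.002),
                                     e3 = mk(numeric(0))),
                                electrodes = c("e1", "e2", "e3"))
  expect_equal(nrow(none), 0L)
  expect_error(detect_network_bursts(list(), electrodes = character(0)),
               "empty")
})

test_that("firing rate is count over duration", {
  expect_equal(firing_rate(seq_len(600) / 10, 100), 6)
  expect_equal(firing_rate(numeric(0), 10), 0)
  expect_error(firing_rate(1:3, 0), "> 0")
  tr <- poisson_train_set(1, 5, 200, seed = 47)$trains[[1]]
  expect_equal(firing_rate(tr, 200), 5, tolerance = 0.1)
})

test_that("cross-correlogram directionality recovers imposed lags", {
  a <- poisson_train_set(1, 8, 100, seed = 51)$trains[[1]]
  b <- a + 0.002
  b <- b[b < 100]
  d <- directionality(a, b, 100)
  expect_equal(d$peak_lag_ms, 2)
  expect_gt(d$asymmetry, 0)

  auto <- directionality(a, a, 100)
  expect_equal(auto$peak_lag_ms, 0)
  expect_lt(abs(auto$asymmetry), 0.1)

  null_ok <- vapply(1:10, function(s) {
    pair <- poisson_train_set(2, 5, 300, seed = 510 + s)
    abs(directionality(pair$trains[[1]], pair$trains[[2]],
                       300)$asymmetry) < 0.1
  }, logical(1))
  expect_gte(sum(null_ok), 9)
})

test_that("synchrony summaries report bounded metrics and rates", {
  cfg <- sim_config(n_neurons = 4, duration = 60, mean_rate = 0.5,
                    burst_rate = 0.5, spikes_per_burst = 4,
                    sync_jitter_ms = 2, seed = 53)
  tr <- simulate_spike_trains(cfg)$spikes
  s <- synchrony_summary(tr)
  expect_gt(s$spike_contrast, 0)
  expect_lte(s$spike_contrast, 1)
  expect_gt(s$participation_ratio, 0)
  expect_lte(s$participation_ratio, 1)
  expect_gte(s$network_burst_rate_per_min, 0)
  expect_lt(s$mean_rate_hz, 6)  # the sparse-firing regime
})
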