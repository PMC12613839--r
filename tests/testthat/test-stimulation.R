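test_that("evoked responses enforce the window and amplitude gates", {
  onset <- 1
  rec <- synthetic_peak_recording(1, 3, events = data.frame(
    channel = c(1, 1, 1),
    t = c(onset + 0.020, onset + 0.060, onset + 0.200),
    amp_uv = c(-80, -30, -80)), noise_sd = 3, seed = 7)
  resp <- extract_evoked_responses(rec, onset)
  # -80 uV at +20 ms passes; 30 uV fails the >50 uV gate;
  # +200 ms falls outside the 150 ms window
  expect_equal(resp$stims$n_aps, 1L)
  expect_equal(resp$aps$latency_ms, 20, tolerance = 0.2)
  expect_lt(resp$aps$amp_uv, -50)
})

test_that("empty responses are retained as failures", {
  rec <- synthetic_peak_recording(1, 3, noise_sd = 3, seed = 8)
  resp <- extract_evoked_responses(rec, c(0.5, 1.5))
  expect_equal(nrow(resp$stims), 2L)
  expect_equal(resp$stims$n_aps, c(0L, 0L))
  expect_true(all(is.na(resp$stims$first_latency_ms)))
})

test_that("every reported AP satisfies both gates under random protocols", {
  withr::with_seed(9, {
    for (i in 1:5) {
      n_ev <- 30
      ev <- data.frame(channel = 1,
                       t = sort(runif(n_ev, 0.2, 9.8)),
                       amp_uv = sample(c(-30, -45, -70, -120), n_ev,
                                       replace = TRUE))
      rec <- synthetic_peak_recording(1, 10, events = ev, noise_sd = 3,
                                      seed = 90 + i)
      onsets <- seq(0.3, 9, by = 0.7)
      resp <- extract_evoked_responses(rec, onsets, window_ms = 150,
                                       min_amp_uv = 50)
      if (nrow(resp$aps)) {
        expect_true(all(abs(resp$aps$amp_uv) > 50))
        expect_true(all(resp$aps$latency_ms > 0 &
                          resp$aps$latency_ms <= 150))
      }
    }
  })
})

test_that("overlapping windows truncate at the next onset and flag it", {
  # 10 Hz: 100 ms period, shorter than the 150 ms response window
  onsets <- seq(0.5, 1.5, by = 0.1)
  rec <- synthetic_peak_recording(1, 3, events = data.frame(
    channel = 1, t = onsets[1] + 0.180, amp_uv = -90), noise_sd = 3,
    seed = 10)
  resp <- extract_evoked_responses(rec, onsets)
  expect_true(all(resp$stims$truncated[-length(onsets)]))
  expect_false(resp$stims$truncated[length(onsets)])
  # the -90 uV peak at +180 ms belongs to the *second* window, not the first
  expect_equal(resp$stims$n_aps[1], 0L)
  expect_equal(resp$stims$n_aps[2], 1L)
})

test_that("latency and delta-latency statistics match hand constructions", {
  onsets <- (1:10) / 2
  ev <- data.frame(channel = 1, t = onsets + 0.012, amp_uv = -80)
  rec <- synthetic_peak_recording(1, 6, events = ev, noise_sd = 3, seed = 11)
  resp <- extract_evoked_responses(rec, onsets)
  st <- latency_stats(resp)
  expect_equal(st$latency$mean, 12, tolerance = 0.2)
  expect_equal(st$latency$n, 10L)
  expect_equal(nrow(st$delta), 0L)  # single APs: no delta latencies

  # two APs at +10 and +25 ms: delta latency 15 ms
  ev2 <- rbind(data.frame(channel = 1, t = onsets + 0.010, amp_uv = -80),
               data.frame(channel = 1, t = onsets + 0.025, amp_uv = -80))
  rec2 <- synthetic_peak_recording(1, 6, events = ev2, noise_sd = 3,
                                   seed = 12)
  st2 <- latency_stats(extract_evoked_responses(rec2, onsets))
  expect_equal(st2$delta$mean, 15, tolerance = 0.3)
  expect_equal(st2$latency$mean, 10, tolerance = 0.2)
})

test_that("latencies are invariant to a recording-wide time shift", {
  ev <- data.frame(channel = 1, t = c(1.01, 2.015), amp_uv = -80)
  rec <- synthetic_peak_recording(1, 4, events = ev, noise_sd = 3, seed = 13)
  r1 <- extract_evoked_responses(rec, c(1, 2))
  shifted <- rec
  shifted$t0 <- 5
  r2 <- extract_evoked_responses(shifted, c(6, 7))
  expect_equal(r1$stims$first_latency_ms, r2$stims$first_latency_ms,
               tolerance = 1e-9)
})

test_that("latency drift across a pulse train is recovered within 0.5 ms", {
  lay <- build_circuit_layout(1, 200)
  cfg <- sim_config(n_neurons = 1, duration = 12, mean_rate = 0,
                    burst_rate = 0, noise_sd = 4, template_amp_uv = -80,
                    n_background_channels = 0)
  drift <- simulate_stim_protocol("optogenetic", n_pulses = 10, freq_hz = 1,
                                  pulse_ms = 50,
                                  response = list(latency_ms = 10,
                                                  jitter_ms = 0.1,
                                                  drift_ms_per_pulse = 2),
                                  seed = 14)
  flat <- simulate_stim_protocol("optogenetic", n_pulses = 10, freq_hz = 0.5,
                                 pulse_ms = 50, t_start = 0.1,
                                 response = list(latency_ms = 10,
                                                 jitter_ms = 0.1,
                                                 drift_ms_per_pulse = 0),
                                 seed = 15)
  recover <- function(pr, dur) {
    sp <- spike_train_set(list(n1 = pr$truth$t), duration = dur)
    r <- render_extracellular(sp, lay, cfg, seed = 16)
    rec <- highpass_filter(r$rec)
    latency_stats(extract_evoked_responses(rec, pr$stim),
                  groups = rep("g", nrow(pr$stim)))
  }
  st_d <- recover(drift, 12)
  # configured mean latency: 10 + 2 * mean(0:9) = 19 ms
  expect_equal(st_d$latency$mean, 19, tolerance = 0.5 / 19)
  cfg$duration <- 20
  st_f <- recover(flat, 20)
  expect_equal(st_f$latency$mean, 10, tolerance = 0.5 / 10)
})

test_that("artifact blanking removes transients without touching other APs", {
  fs <- 25000
  ev <- data.frame(channel = 1, t = c(0.8, 1.25), amp_uv = c(-80, -80))
  rec <- synthetic_peak_recording(1, 2, events = ev, noise_sd = 3, seed = 17)
  # electrical artifact: huge biphasic transient at 1.0 s
  art <- time_to_sample(1, fs)
  rec$data[1, art:(art + 2)] <- 2000
  rec$data[1, (art + 3):(art + 5)] <- -2000
  blanked <- blank_stim_artifacts(rec, 1, blank_ms = 2)
  expect_lt(max(abs(blanked$data[1, art:(art + 5)])), 50)
  pk <- detect_peaks_frame(blanked)
  keep <- pk$t
  expect_equal(length(keep), 2L)
  expect_equal(sort(keep), c(0.8, 1.25), tolerance = 1e-3)
})

test_that("stimulation efficacy tables report medians and fold-changes", {
  rates <- data.frame(circuit = c("c1", "c1"), n_neurons = 1,
                      condition = c("baseline", "stim"), rate_hz = c(2, 2))
  eff <- stim_efficacy_by_count(rates)
  expect_equal(eff$fold_change, 1)
  expect_equal(nrow(eff), 1L)

  expect_error(stim_efficacy_by_count(
    data.frame(circuit = "c1", n_neurons = 1, condition = "stim",
               rate_hz = 1)), "baseline")
})

test_that("a superlinear evoked-rate law is recovered from simulated epochs", {
  # rates r0 * 2^(n-1): simulate stim epochs as Poisson trains at that rate
  r0 <- 1.5
  rows <- list()
  withr::with_seed(19, {
    for (n in 1:4) {
      for (circ in 1:10) {
        base <- length(poisson_train_set(1, r0, 60)$trains[[1]]) / 60
        stim <- length(poisson_train_set(1, r0 * 2^(n - 1), 60)$trains[[1]]) / 60
        rows[[length(rows) + 1L]] <- data.frame(
          circuit = paste0("c", n, "_", circ), n_neurons = n,
          condition = c("baseline", "stim"), rate_hz = c(base, stim))
      }
    }
  })
  eff <- stim_efficacy_by_count(do.call(rbind, rows))
  expect_equal(eff$fold_change, 2^(0:3), tolerance = 0.1)
})
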