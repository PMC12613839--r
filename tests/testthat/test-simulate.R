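test_that("regular layouts have pitch-spaced path distances and segment labels", {
  lay <- build_circuit_layout(5, 200)
  expect_equal(path_distances(lay, lay$paths[[1]]), rep(200, 4))

  single <- build_circuit_layout(1, 200)
  expect_equal(path_distances(single, single$paths[[1]]), numeric(0))

  seg <- data.frame(label = c("individual", "bundled"),
                    start_um = c(0, 200), end_um = c(200, 800))
  lay2 <- build_circuit_layout(5, 200, segment_spec = seg)
  # pair midpoints 100, 300, 500, 700 um -> individual, bundled x3
  mids <- c(100, 300, 500, 700)
  expect_equal(segment_at(seg, mids),
               c("individual", "bundled", "bundled", "bundled"))
  expect_error(build_circuit_layout(5, 200, segment_spec = data.frame(
    label = "partial", start_um = 0, end_um = 300)), "cover")
})

test_that("velocity model is v0/(1 + c(n-1)) and monotone", {
  expect_equal(velocity_model(1, 0.7, 0.9), 0.7)     # lone AP: always v0
  expect_equal(velocity_model(3, 1.2, 0), 1.2)       # no coupling: always v0
  expect_equal(velocity_model(3, 1.0, 0.25), 1 / 1.5)
  v <- velocity_model(1:4, 1.0, 0.25)
  expect_true(all(diff(v) < 0))
  expect_error(velocity_model(0, 1, 0.1), ">= 1")
})

test_that("spike-train generator honours rate, degeneracy and jitter limits", {
  # degenerate config: no spikes at all
  cfg0 <- sim_config(n_neurons = 2, duration = 10, mean_rate = 0,
                     burst_rate = 0, seed = 1)
  expect_equal(sum(lengths(simulate_spike_trains(cfg0)$spikes$trains)), 0L)

  # homogeneous Poisson 5 Hz, 100 s: count within 500 +/- 3*sqrt(500)
  counts <- vapply(1:20, function(s) {
    cfg <- sim_config(n_neurons = 1, duration = 100, mean_rate = 5,
                      burst_rate = 0, seed = s)
    length(simulate_spike_trains(cfg)$spikes$trains[[1]])
  }, numeric(1))
  expect_true(mean(abs(counts - 500) <= 3 * sqrt(500)) >= 0.95)

  # zero jitter, pure shared-burst mode: all trains identical
  cfgj <- sim_config(n_neurons = 4, duration = 30, mean_rate = 0,
                     burst_rate = 1, spikes_per_burst = 3,
                     sync_jitter_ms = 0, seed = 9)
  tr <- simulate_spike_trains(cfgj)$spikes$trains
  for (i in 2:4) expect_identical(tr[[i]], tr[[1]])
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_neurons = 3, duration = 5, seed = 77,
                    n_background_channels = 2)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$rec$data, b$rec$data)
  expect_identical(a$spikes$trains, b$spikes$trains)
  expect_identical(a$truth, b$truth)
})

test_that("rendered APs propagate with delay = distance / velocity", {
  lay <- build_circuit_layout(2, 200)
  cfg <- sim_config(n_neurons = 1, duration = 1, noise_sd = 0, v0 = 1,
                    coupling = 0, n_background_channels = 0, fs = 25000)
  # one spike exactly on the sample grid
  sp <- spike_train_set(list(n1 = 0.5), duration = 1)
  r <- render_extracellular(sp, lay, cfg)
  t1 <- which.min(r$rec$data[1, ])
  t2 <- which.min(r$rec$data[2, ])
  # 200 um at 1 m/s = 0.2 ms = 5 samples at 25 kHz
  expect_equal(t2 - t1, 5L)
  # template extremum is placed at the spike sample with its full amplitude
  expect_equal(min(r$rec$data), -60)
  expect_equal(t1, time_to_sample(0.5, 25000))
})

test_that("rendered background noise has the configured MAD level", {
  lay <- build_circuit_layout(2, 200)
  cfg <- sim_config(n_neurons = 1, duration = 10, mean_rate = 0,
                    burst_rate = 0, noise_sd = 5,
                    n_background_channels = 0)
  sp <- spike_train_set(list(n1 = numeric(0)), duration = 10)
  r <- render_extracellular(sp, lay, cfg, seed = 21)
  for (ch in 1:2) {
    expect_equal(noise_level_mad(r$rec$data[ch, ]), 5, tolerance = 0.05)
  }
})

test_that("co-active axon counts drive per-AP velocities in ground truth", {
  cfg <- sim_config(n_neurons = 3, duration = 20, mean_rate = 0,
                    burst_rate = 1.5, spikes_per_burst = 1,
                    sync_jitter_ms = 0, v0 = 1, coupling = 0.25, seed = 31)
  sim <- simulate_recording(cfg)
  expect_true(all(sim$truth$n_active == 3))
  expect_equal(unique(sim$truth$velocity), 1 / 1.5)
})

test_that("channel occupancy follows the cylinder-packing formula", {
  # four 1-um axons in a 5 x 30 um channel: pi/150, about 2%
  occ <- channel_occupancy_fraction(4, 1, 5, 30)
  expect_equal(occ, pi / 150)
  expect_equal(round(occ, 2), 0.02)
  expect_equal(channel_occupancy_fraction(0, 1, 5, 30), 0)
  # one 1-um axon in the 5 x 20 um (Y-shape) channel
  expect_equal(channel_occupancy_fraction(1, 1, 5, 20), pi / 4 / 100)
  expect_warning(channel_occupancy_fraction(1000, 10, 5, 20), "non-physical")
})

test_that("stimulation protocols produce the documented schedules", {
  el <- simulate_stim_protocol("electrical")
  expect_equal(nrow(el$stim), 30L)
  # 1800 ms interpulse interval plus the 200 us biphasic pulse
  expect_equal(unique(round(diff(el$stim$onset), 6)), 1.8002)

  op <- simulate_stim_protocol("optogenetic", n_pulses = 10, freq_hz = 2,
                               pulse_ms = 50)
  expect_equal(op$stim$onset, seq(0, 4.5, by = 0.5))

  none <- simulate_stim_protocol("optogenetic", n_pulses = 0)
  expect_equal(nrow(none$stim), 0L)
  expect_equal(nrow(none$truth), 0L)

  expect_error(simulate_stim_protocol("optogenetic", freq_hz = 25,
                                      pulse_ms = 50), "overlap")
})

test_that("evoked ground truth follows latency, drift and AP-count settings", {
  pr <- simulate_stim_protocol("optogenetic", n_pulses = 5, freq_hz = 1,
                               pulse_ms = 50,
                               response = list(latency_ms = 10,
                                               jitter_ms = 0, n_aps = 2,
                                               delta_ms = 15,
                                               drift_ms_per_pulse = 2),
                               seed = 3)
  first <- pr$truth[pr$truth$ap == 1, ]
  expect_equal((first$t - pr$stim$onset) * 1000, 10 + 2 * (0:4))
  second <- pr$truth[pr$truth$ap == 2, ]
  expect_equal((second$t - first$t) * 1000, rep(15, 5))
})
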