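#!/usr/bin/env Rscript
# Stage 1: build the synthetic study set.
#
# Simulates microchannel circuits with 1-4 axons on a 5-electrode path
# (200 um pitch), under the sparse, burst-dominated firing regime, and
# renders extracellular recordings with known per-AP conduction velocities.
# Also simulates a two-segment circuit (individual vs bundled axon spans)
# and a baseline/blocker-like condition pair for the dynamics stage.

suppressPackageStartupMessages(library(meacircuit))

out_dir <- "results/simulated"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed0 <- 20260930L

lay <- build_circuit_layout(5, pitch_um = 200)
write_layout(lay, file.path(out_dir, "layout.json"))

message("Rendering circuits with n = 1..4 axons (coupling 0.25) ...")
for (n in 1:4) {
  cfg <- sim_config(n_neurons = n, duration = 20, mean_rate = 0,
                    burst_rate = 2, spikes_per_burst = 1,
                    sync_jitter_ms = 0, v0 = 1, coupling = 0.25,
                    noise_sd = 5, seed = seed0 + n)
  sim <- simulate_recording(cfg, layout = lay)
  write_recording(sim$rec, file.path(out_dir, sprintf("circuit_n%d", n)))
  write_spike_trains(sim$spikes, file.path(out_dir,
                                           sprintf("truth_trains_n%d.json", n)))
  write_metrics(sim$truth, file.path(out_dir, sprintf("truth_aps_n%d.csv", n)))
  message(sprintf("  n=%d: %d APs, assigned velocity %.3f m/s",
                  n, nrow(sim$truth), unique(sim$truth$velocity)[1]))
}

message("Rendering the two-segment circuit (individual 1.0 / bundled 0.6 m/s) ...")
seg <- data.frame(label = c("individual", "bundled"),
                  start_um = c(0, 200), end_um = c(200, 800))
lay_seg <- build_circuit_layout(5, 200, segment_spec = seg)
write_layout(lay_seg, file.path(out_dir, "layout_segments.json"))
cfg_seg <- sim_config(n_neurons = 1, duration = 20, mean_rate = 0,
                      burst_rate = 2, spikes_per_burst = 1,
                      sync_jitter_ms = 0, noise_sd = 5, seed = seed0 + 10L)
sim_seg <- simulate_recording(cfg_seg, layout = lay_seg,
                              segment_velocities = c(individual = 1.0,
                                                     bundled = 0.6))
write_recording(sim_seg$rec, file.path(out_dir, "circuit_segments"))

message("Simulating a baseline vs blocker-like condition pair ...")
# baseline: bursty synchronous activity; "treated": same mean rate but
# tonic and desynchronised, emulating the loss of synaptic drive
base_cfg <- sim_config(n_neurons = 4, duration = 120, mean_rate = 1,
                       burst_rate = 1, spikes_per_burst = 4,
                       sync_jitter_ms = 2, seed = seed0 + 20L)
trt_cfg <- sim_config(n_neurons = 4, duration = 120, mean_rate = 5,
                      burst_rate = 0, seed = seed0 + 21L)
write_spike_trains(simulate_spike_trains(base_cfg)$spikes,
                   file.path(out_dir, "trains_baseline.json"))
write_spike_trains(simulate_spike_trains(trt_cfg)$spikes,
                   file.path(out_dir, "trains_treated.json"))

message("Done: inputs for stages 2-5 are under ", out_dir)
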