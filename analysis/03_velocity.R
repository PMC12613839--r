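#!/usr/bin/env Rscript
# Stage 3: conduction-velocity estimation.
#
# Runs the baseline-SD threshold-crossing estimator (10 ms baseline window,
# 5 SD crossing, contamination rejection, >= 10 accepted APs per summary)
# along the known electrode geometry of each simulated circuit, compares
# median recovered velocity with the assigned ground truth across axon
# counts, and summarises the two-segment circuit by segment.

suppressPackageStartupMessages(library(meacircuit))

in_sim <- "results/simulated"
in_det <- "results/detect"
out_dir <- "results/velocity"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

lay <- read_layout(file.path(in_sim, "layout.json"))
rows <- list()
for (n in 1:4) {
  stem <- sprintf("circuit_n%d", n)
  rec <- read_recording(file.path(in_det, paste0(stem, "_preprocessed")))
  spikes <- read_spike_trains(file.path(in_det, paste0(stem, "_spikes.json")))
  est <- estimate_velocities(rec, lay, spikes = spikes)
  write_metrics(est, file.path(out_dir, sprintf("estimates_n%d.csv", n)))
  truth <- read_metrics(file.path(in_sim, sprintf("truth_aps_n%d.csv", n)))
  acc <- est[est$status == "accepted" & est$pair_type == "consecutive", ]
  rows[[n]] <- data.frame(
    n_neurons = n,
    assigned_m_s = median(truth$velocity),
    recovered_median_m_s = median(acc$velocity),
    rel_error = median(acc$velocity) / median(truth$velocity) - 1,
    n_accepted_aps = length(unique(acc$ap_id)),
    n_rejected = length(unique(est$ap_id[est$status != "accepted"])))
  message(sprintf(
    "n=%d: assigned %.3f m/s, recovered median %.3f m/s (%+.1f%%), %d APs",
    n, rows[[n]]$assigned_m_s, rows[[n]]$recovered_median_m_s,
    100 * rows[[n]]$rel_error, rows[[n]]$n_accepted_aps))
}
summary_tab <- do.call(rbind, rows)
write_metrics(summary_tab, file.path(out_dir, "velocity_by_count.csv"))
if (all(diff(summary_tab$recovered_median_m_s) < 0)) {
  message("Recovered median velocity decreases monotonically with axon count.")
}

lay_seg <- read_layout(file.path(in_sim, "layout_segments.json"))
rec_seg <- read_recording(file.path(in_det, "circuit_segments_preprocessed"))
sp_seg <- read_spike_trains(file.path(in_det, "circuit_segments_spikes.json"))
seg_est <- estimate_velocities(rec_seg, lay_seg, spikes = sp_seg)
seg_sum <- velocity_by_segment(seg_est)
write_metrics(seg_est, file.path(out_dir, "estimates_segments.csv"))
write_metrics(seg_sum, file.path(out_dir, "velocity_by_segment.csv"))
message("Segment medians (m/s):")
print(seg_sum)
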