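---
title: "Methods: analysing few-neuron microcircuit recordings on MEAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing few-neuron microcircuit recordings on MEAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meacircuit)
```

## The setting

`meacircuit` analyses extracellular recordings of very small neuronal
circuits — one to four neurons whose axons run together through narrow
microchannels (5 um high, 20–30 um wide) over the electrodes of a
multielectrode array (MEA; 60 electrodes at 200 um pitch). Because the
electrode geometry along a microchannel is known from the microfluidic
design, the arrival time of an action potential (AP) at successive
electrodes yields its conduction velocity; because the circuits are tiny
and their firing is sparse and burst-dominated, several standard analysis
tools (spike sorting above all) fail, and the pipeline is built around
sorting-free, electrode-wise statistics instead.

Internal units are fixed everywhere: seconds, microvolts, micrometres,
metres per second. Conversions happen only at I/O boundaries (the binary
recording container declares a `scale_to_uv` factor). Timestamps are
real-valued seconds at every interface; conversion to sample indices is
floor-based (`time_to_sample()`), and the one place where sub-sample
precision matters (threshold crossings, below) interpolates explicitly.

## Preprocessing

Traces are conditioned by a second-order Butterworth high-pass at 100 Hz
followed by global common median referencing (CMR): at every sample the
across-channel median is subtracted from every channel, removing
array-wide artifacts while leaving signals confined to a few channels
untouched.

Two choices deserve comment:

* **Zero-phase filtering.** The filter is applied forward and backward
  (effective response $|H(f)|^2$), so no channel-uniform group delay is
  introduced. Relative inter-electrode delays — the velocity signal — are
  unaffected by either choice; absolute latencies (stimulation analysis)
  could shift by a fraction of the AP width under causal filtering, which
  is why the choice is fixed and documented. Edges are reflect-padded by
  three filter time constants; the padded spans are recorded in the
  recording metadata. The inner IIR loop is compiled (Rcpp); coefficients
  come from `signal::butter`, and the implementation matches
  `signal::filtfilt` to machine precision away from the edges.
* **Order of filter and CMR.** The median is nonlinear, so
  filter-then-CMR and CMR-then-filter do *not* commute exactly: they agree
  only when the per-sample median is structurally pinned (the test suite
  verifies exact agreement on an antisymmetric construction, and a bounded,
  sub-noise discrepancy on independent noise). The pipeline fixes the
  order to filter first, then reference.
* **CMR needs a majority of quiet channels.** On a recording containing
  only the five electrodes of one microchannel, an AP present on most
  channels leaks into the median and is re-injected (inverted) everywhere.
  On the full 60-electrode array any one circuit occupies a small minority
  of channels and CMR is benign. The simulator therefore appends
  noise-only "background" channels (`n_background_channels`) to rendered
  recordings; validation of detection statistics uses the full 60-channel
  complement.

## Spike detection

Spike sorting is deliberately out of scope: in these circuits, waveform
superposition during synchronous bursts and multi-electrode pickup of
single neurons make sorters unreliable, so detection is electrode-wise.
A sample is a spike iff it lies below $-k \cdot \mathrm{MAD}$ (negative
signs only by default, $k = 5$) and is the minimum within a
$\pm 0.2$ ms exclusion sweep; ties go to the earliest sample. The MAD is
`median(|x - median(x)|) * 1.4826` — scaled to estimate the Gaussian SD —
computed on the full trace, spikes included; at sparse rates (below 6 Hz
per electrode) the robust estimator is essentially uncontaminated. The
unscaled variant is available via `mad_scale = 1`.

## Conduction velocity

Peak timestamps are not reliable reference points across electrodes
(superposition and waveform change during propagation), so the estimator
uses the initial rising phase of the voltage instead:

1. A *seed time* is placed about 1 ms before a detected AP on the first
   path electrode (`seed = peak - 1 ms`; a manual seed list is accepted,
   mirroring manual spike selection).
2. On each electrode, the baseline mean and SD are computed over the 10 ms
   window immediately preceding the seed. If any detected spike falls in
   that window the AP is **rejected** (`rejected_contaminated`) — the SD
   would be distorted.
3. The crossing is the first sample whose deviation from the baseline mean
   exceeds 5 baseline SDs, searched within a horizon that is widened per
   electrode by the slowest plausible propagation delay (velocity prior
   0.1–10 m/s), so downstream crossings of the same AP are found without
   mismatching later bursts. "Rose beyond" is interpreted as magnitude
   departure (configurable polarity), appropriate for negative-going
   extracellular spikes.
4. Velocities are distance over crossing-time difference for consecutive
   accepted electrode pairs (end-to-end pairs are reported as well,
   flagged separately); $\Delta t \le 0$ is rejected as below the time
   resolution. Summaries (median, IQR) are emitted per geometry segment
   only when at least 10 distinct accepted APs support them.

**Sub-sample interpolation.** Crossing times quantised to the sample grid
bias the estimate: at 25 kHz, a 200 um pitch and 0.8 m/s, the true
inter-electrode delay is 6.25 samples, and the floor-quantised median sits
at 6 samples (a +4% bias). The crossing is therefore refined by linear
interpolation between the last sub-threshold and first supra-threshold
samples; a crossing that lands exactly on a sample is returned unchanged,
and the constructed-ramp test covers that case. With interpolation,
ground-truth recovery on simulated circuits is within ~0.5% at the
default noise level.

## ISI statistics and condition comparison

Interspike-interval (ISI) histograms use 1 ms bins with a 1000 ms overflow
cap (configurable; intervals beyond the cap are pooled but counted).
Baseline and treated conditions of the same electrode are compared by the
Kullback–Leibler divergence
$KL(P, Q) = \sum_x P(x) \log\left(P(x)/Q(x)\right)$ in natural log units.
Electrodes where either condition has 400 or fewer intervals are excluded
(sparse histograms make the divergence erratic) and reported as skipped.

Empty bins would make the divergence infinite, so both probability vectors
receive additive smoothing of $\varepsilon$ per bin (renormalised), with
$\varepsilon = 1/(n_P + n_Q)$ by default — one pseudo-count spread over
the pooled sample size. `epsilon = 0` evaluates the bare formula (used by
the exactness tests). The divergence is asymmetric by construction; the
pipeline always reports $KL(\mathrm{baseline}, \mathrm{treated})$.

## Synchrony

**Spike contrast** scans a geometric grid of bin sizes from half the
recording span down to `max(min_isi/2, min_bin)` (shrink factor 0.9,
`min_bin` 10 ms — the defaults of the algorithm's reference
implementation). At each bin size, spikes of all trains are pooled into
half-overlapping bins; the synchrony curve is the product of a contrast
term, $\sum_k |\theta_{k+1} - \theta_k| / (2M)$ with $M$ the total spike
count, and an active-train term, the spike-weighted mean fraction of
trains active per occupied bin rescaled to $[0, 1]$. The synchrony value
is the curve maximum: exactly 1 for identical trains whose ISIs exceed the
smallest bin, near 0 for independent trains. The implementation is checked
against a naive, loop-based reference implementation written directly from
the published definition.

**Participation ratio.** Trains are binned to counts (5 ms), the pairwise
Pearson correlation matrix is formed, and
$PR = \left(\sum_i \lambda_i\right)^2 / \left(N \sum_i \lambda_i^2\right)$
over its eigenvalues. Decoupled activity gives $PR \to 1$; rank-one
(fully coupled) activity gives exactly $1/N$. Zero-variance trains cannot
enter a correlation matrix and are dropped from $N$ with a warning rather
than imputed.

**Bursts** use the MaxInterval rule set (maximum in-burst ISI 10 ms,
minimum 3 spikes, minimum duration 1 ms, minimum interburst interval
200 ms) with a single ISI threshold serving as both start and continuation
criterion. Candidate bursts (runs of $\ge 2$ spikes) closer than 200 ms
are merged, absorbing any lone spikes inside the merged span — so a merged
burst can legitimately contain an internal gap longer than the in-burst
ISI maximum, which is the classical behaviour of the method. The detector
is property-tested against a brute-force enumeration of the same rules.

**Network bursts** are onset coincidences: an event where every *active*
electrode (each electrode with at least one burst; a strict explicit set
is available) has a burst onset within a common 5 ms window. The event
time is the earliest onset, and onsets consumed by one event are not
reused.

**Directionality** is a binned cross-correlogram (1 ms bins, ±50 ms lags);
the peak lag and the asymmetry index
$(\mathrm{area}_{+} - \mathrm{area}_{-}) / \mathrm{total}$ confirm
direction of propagation between two electrodes.

## Stimulation responses

For each stimulus onset, detected AP peaks in the 150 ms window after the
onset are collected; peaks with amplitude magnitude of 50 uV or less are
excluded as artifacts. Windows that would cross the next onset (pulse
periods shorter than the window) are truncated there and flagged. First-AP
latency is onset-to-peak; delta latencies are the delays between
consecutive AP peaks within one response; summaries are per group
(frequency, intensity, ...). Stimuli with no surviving peak are retained
as failures. For electrical stimulation, samples within ±2 ms of each
pulse are blanked by linear interpolation *before* detection; a span
clipped at a trace edge is filled flat from its one clean boundary.
Response peaks are read from all circuit electrodes and reported per
electrode.

## The simulator

The generator emulates the recording conditions the analysis targets, and
its defaults are the study conditions:

| Parameter | Default | What it emulates |
|---|---|---|
| `n_neurons` | 1 (1–4 typical) | axons per microchannel |
| `mean_rate` + bursts | ~5 Hz total | sparse firing, below 6 Hz |
| `burst_rate`, `spikes_per_burst` | 0.8 Hz × 5 | dense shared bursts |
| `sync_jitter_ms` | 2 ms | inter-neuron burst synchrony |
| `v0`, `coupling` | 1 m/s, 0.25 | conduction and its slowing |
| `noise_sd` | 5 uV | background noise (MAD ≈ 5 uV) |
| `template_amp_uv`, width | −60 uV, 1 ms | biphasic extracellular AP |
| `fs` | 25 kHz | acquisition rate (configurable; all timing parameters are in ms, so results are fs-robust) |

Per AP, the number of co-active axons (spikes of distinct neurons within
±1 ms) sets the velocity through the minimal monotone law
$v = v_0 / (1 + c\,(n_\mathrm{active} - 1))$ — a stand-in chosen for its
monotonicity, not a biophysical model. The AP template is a
monotone-cubic spline through fixed control points (sharp trough at 30% of
the width reaching exactly the configured amplitude, shallow positive
rebound); monotone interpolation guarantees the rendered extremum equals
the configured amplitude exactly. Templates are evaluated at continuous
(fractional-sample) offsets, so assigned velocities are not quantised into
the render; ground truth keeps continuous times while rendered traces are
sampled. Noise is white Gaussian. A piecewise velocity profile along the
path (`segment_velocities`) renders circuits whose individual and bundled
segments propagate at different speeds.

What the simulator does **not** model: biophysical (cable-equation) field
interactions, LFP, electrode drift, waveform change during propagation,
amplitude attenuation with distance (off by default), ionic-concentration
effects, spatial noise correlation. Passing the validation suite therefore
shows that the *estimators recover what they claim to estimate under
controlled conditions* — it does not certify performance on lab data with
waveform variability the generator does not produce.

## Numerical choices

* ISI binning guards against float error pushing an exactly-on-boundary
  interval down a bin (`floor(x/bin + 1e-9)`).
* Detection ties inside the exclusion sweep break to the earliest sample;
  equal-depth troughs yield exactly one detection.
* The channel median over an even channel count is the mean of the two
  central values.
* Degenerate inputs: empty trains yield empty histograms (`n_isi = 0`),
  zero-duration errors are raised early, a single channel passes CMR
  unchanged with a warning, all-zero traces yield `rejected_no_crossing`,
  and degenerate (constant) binned trains are an error for the
  cross-correlogram.
* Seeds: every simulation entry point takes one integer seed; identical
  configurations and seeds give bit-identical outputs, and the caller's
  RNG state is restored.

## Problem sizes used in validation

The automated validation runs at desk scale: 20 s recordings at 25 kHz
for velocity and detection checks (10 seeds for the statistical ones;
the full 60-channel array for detection fidelity), 120 s spike-train sets
for the KL and jitter-sweep checks, 600 s train sets for the
participation-ratio anchors, 100+ random circuits for the PR bound, 1000
random trains for the burst oracle and 25 train sets for the
spike-contrast oracle. Group-level hypothesis testing (rank tests, outlier
removal) is intentionally excluded: the pipeline exports metric tables and
leaves significance testing to standard external routines.

## Known limitations

* The recording container is a flat binary + JSON sidecar dialect; no
  HDF5 reader is bundled in this build, and vendor acquisition formats are
  out of scope.
* The velocity-vs-count law and the shared-burst generator are
  deliberately minimal; they provide ground truth for estimator
  validation, not biophysical predictions.
* Spike-contrast hyperparameters below the 10 ms bin floor are not
  explored; synchrony structure at finer timescales than the floor will
  saturate the measure for sparse trains.
* CMR order sensitivity (above) and its small-array distortion are
  documented rather than corrected; use background channels or the full
  array.
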