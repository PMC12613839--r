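#' Simulation configuration for a synthetic microchannel circuit
#'
#' Defaults emulate the recording conditions the analysis targets: 1-4 axons
#' per microchannel, sparse firing (about 5 Hz per neuron, i.e. below 6 Hz on
#' average), activity dominated by dense shared bursts, baseline conduction
#' velocity 1 m/s slowed by co-active axons, biphasic ~60 uV action-potential
#' waveforms on ~5 uV (MAD) Gaussian background noise at 25 kHz.
#'
#' @param n_neurons number of axons in the channel (1-4 typically)
#' @param duration recording length (s)
#' @param mean_rate tonic (non-burst) Poisson rate per neuron (Hz)
#' @param burst_rate rate of shared network burst events (Hz)
#' @param spikes_per_burst spikes each neuron fires per burst event
#' @param intra_burst_isi_ms fixed interspike interval inside a burst (ms)
#' @param sync_jitter_ms SD of per-neuron Gaussian jitter of burst onset
#'   times around the shared event (ms); 0 gives perfectly synchronous bursts
#' @param refractory_ms minimum interval enforced between spikes of one
#'   neuron (ms)
#' @param v0 conduction velocity of a lone AP (m/s)
#' @param coupling ephaptic slowing coefficient (>= 0); see [velocity_model()]
#' @param coincidence_ms half-width of the window used to count co-active
#'   axons for an AP (ms)
#' @param noise_sd SD of white Gaussian background noise (uV)
#' @param n_background_channels noise-only channels appended to rendered
#'   recordings, emulating the rest of the electrode array outside this
#'   circuit; they keep the global common median reference benign, as on a
#'   full 60-electrode grid where any one microchannel occupies a minority
#'   of channels
#' @param template_amp_uv AP template extremum (uV; negative-going)
#' @param template_width_ms total AP template width (ms)
#' @param fs sampling rate for rendered recordings (Hz)
#' @param seed integer RNG seed, or NULL to use the current RNG state
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_neurons = 1, duration = 60, mean_rate = 1,
                       burst_rate = 0.8, spikes_per_burst = 5,
                       intra_burst_isi_ms = 8, sync_jitter_ms = 2,
                       refractory_ms = 1, v0 = 1.0, coupling = 0.25,
                       coincidence_ms = 1, noise_sd = 5,
                       n_background_channels = 10,
                       template_amp_uv = -60, template_width_ms = 1,
                       fs = 25000, seed = NULL) {
  cfg <- list(n_neurons = n_neurons, duration = duration,
              mean_rate = mean_rate, burst_rate = burst_rate,
              spikes_per_burst = spikes_per_burst,
              intra_burst_isi_ms = intra_burst_isi_ms,
              sync_jitter_ms = sync_jitter_ms, refractory_ms = refractory_ms,
              v0 = v0, coupling = coupling, coincidence_ms = coincidence_ms,
              noise_sd = noise_sd,
              n_background_channels = n_background_channels,
              template_amp_uv = template_amp_uv,
              template_width_ms = template_width_ms, fs = fs, seed = seed)
  stopifnot(cfg$duration > 0, cfg$mean_rate >= 0, cfg$burst_rate >= 0,
            cfg$v0 > 0, cfg$coupling >= 0, cfg$noise_sd >= 0, cfg$fs > 0,
            cfg$n_neurons >= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Conduction velocity as a function of co-active axon count
#'
#' Minimal monotone model of activity-dependent conduction slowing in a
#' shared microchannel: `v = v0 / (1 + coupling * (n_active - 1))`. A lone AP
#' propagates at `v0`; each additional co-active axon slows conduction when
#' `coupling > 0`.
#'
#' @param n_active number of co-active axons (>= 1); vectorised
#' @param v0 baseline velocity (m/s)
#' @param coupling slowing coefficient (>= 0)
#' @return velocity in m/s
#' @export
velocity_model <- function(n_active, v0, coupling) {
  if (any(n_active < 1)) stop("`n_active` must be >= 1")
  stopifnot(v0 > 0, coupling >= 0)
  v0 / (1 + coupling * (n_active - 1))
}

#' Build a regular-grid microchannel circuit layout
#'
#' Electrodes are placed on a line at the MEA pitch; segments label distance
#' spans along the path (e.g. individual vs bundled axon regions).
#'
#' @param n_channels_per_path electrodes along the microchannel
#' @param pitch_um electrode spacing (um); 200 for the standard 60-electrode
#'   MEA grid
#' @param segment_spec optional data.frame (`label`, `start_um`, `end_um`)
#'   of non-overlapping spans covering the path
#' @param channel_prefix prefix for generated channel ids
#' @return an `mea_layout` with a single path
#' @export
build_circuit_layout <- function(n_channels_per_path, pitch_um = 200,
                                 segment_spec = NULL,
                                 channel_prefix = "el") {
  stopifnot(pitch_um > 0, n_channels_per_path >= 1)
  ids <- paste0(channel_prefix, seq_len(n_channels_per_path))
  positions <- data.frame(channel_id = ids,
                          x = (seq_len(n_channels_per_path) - 1) * pitch_um,
                          y = 0)
  if (!is.null(segment_spec)) {
    total <- (n_channels_per_path - 1) * pitch_um
    spans <- segment_spec[order(segment_spec$start_um), ]
    covered <- min(spans$start_um) <= 0 && max(spans$end_um) >= total &&
      all(spans$start_um[-1L] == spans$end_um[-nrow(spans)])
    if (n_channels_per_path > 1L && !covered) {
      stop("segment spans must contiguously cover the path (0 to ",
           total, " um)")
    }
  }
  circuit_layout(positions, paths = list(ids),
                 segments = if (is.null(segment_spec)) NULL
                            else list(segment_spec),
                 pitch = pitch_um)
}

#' Simulate spike trains of a shared-burst microcircuit
#'
#' Each neuron fires tonic Poisson spikes at `mean_rate` plus, for every
#' network-level burst event (Poisson at `burst_rate`), a burst of
#' `spikes_per_burst` spikes at fixed intra-burst ISI whose onset is jittered
#' per neuron by `sync_jitter_ms`. This reproduces the bursty, synchronous
#' regime of few-neuron microchannel circuits; lowering the jitter tightens
#' inter-neuron synchrony.
#'
#' @param config a [sim_config()]
#' @return list with `spikes` (an `mea_spiketrains`, one train per neuron,
#'   ids `n1`, `n2`, ...) and `truth` (list with per-neuron spike times and
#'   burst event times)
#' @export
simulate_spike_trains <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  run <- function() {
    dur <- config$duration
    n <- config$n_neurons
    events <- if (config$burst_rate > 0) {
      sort(runif(rpois(1L, config$burst_rate * dur), 0, dur))
    } else numeric(0)
    jit <- if (length(events)) {
      matrix(rnorm(length(events) * n, 0, config$sync_jitter_ms / 1000),
             nrow = length(events), ncol = n)
    } else matrix(numeric(0), 0, n)
    isi <- config$intra_burst_isi_ms / 1000
    offs <- (seq_len(config$spikes_per_burst) - 1L) * isi
    trains <- vector("list", n)
    for (i in seq_len(n)) {
      tonic <- if (config$mean_rate > 0) {
        runif(rpois(1L, config$mean_rate * dur), 0, dur)
      } else numeric(0)
      burst <- if (length(events)) {
        as.vector(outer(events + jit[, i], offs, `+`))
      } else numeric(0)
      tt <- sort(c(tonic, burst))
      tt <- tt[tt >= 0 & tt < dur]
      trains[[i]] <- enforce_refractory(tt, config$refractory_ms / 1000)
    }
    names(trains) <- paste0("n", seq_len(n))
    list(
      spikes = spike_train_set(trains, duration = dur),
      truth = list(spike_times = trains, burst_events = events,
                   config = config)
    )
  }
  if (is.null(config$seed)) run() else with_seed(config$seed, run())
}

# Drop spikes closer than `refractory` (s) to the previously kept spike.
enforce_refractory <- function(times, refractory) {
  if (length(times) < 2L) return(times)
  keep <- logical(length(times))
  keep[1L] <- TRUE
  last <- times[1L]
  for (i in 2L:length(times)) {
    if (times[i] - last > refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Continuous biphasic action-potential template
#'
#' Monotone-cubic (Hermite) spline through fixed control points: a sharp
#' negative trough at 30% of the width reaching exactly `amp_uv`, a zero
#' crossing, and a shallow positive rebound. Returns a function of time (s)
#' relative to template onset; zero outside `[0, width]`.
#'
#' @param amp_uv template extremum in uV (negative for the usual
#'   negative-going extracellular AP)
#' @param width_ms total template width (ms)
#' @return function mapping time offsets (s) to uV
#' @export
ap_template <- function(amp_uv = -60, width_ms = 1) {
  w <- width_ms / 1000
  knots_t <- c(0, 0.15, 0.3, 0.45, 0.55, 0.75, 1) * w
  knots_v <- c(0, 0.25, 1, 0.35, 0, -0.3, 0) * amp_uv
  f <- stats::splinefun(knots_t, knots_v, method = "monoH.FC")
  trough <- 0.3 * w
  out <- function(t_rel) {
    v <- numeric(length(t_rel))
    inside <- t_rel >= 0 & t_rel <= w
    v[inside] <- f(t_rel[inside])
    v
  }
  attr(out, "trough_offset") <- trough
  attr(out, "width") <- w
  out
}

#' Render an extracellular recording from spike trains
#'
#' Places the AP template of every spike on every electrode of the layout
#' path, delayed by the cumulative path distance divided by the AP's assigned
#' conduction velocity, and adds white Gaussian noise. Velocities come from
#' [velocity_model()] applied to the number of axons co-active within
#' `coincidence_ms` of the spike, unless a fixed per-segment velocity profile
#' is supplied. Templates are evaluated at continuous (fractional-sample)
#' offsets; ground truth keeps the continuous spike times.
#'
#' @param spikes an `mea_spiketrains` with one train per neuron
#' @param layout an `mea_layout`; rendering uses `path_id`
#' @param config a [sim_config()] (fs, noise, template, velocity model)
#' @param path_id which layout path to render
#' @param segment_velocities optional named vector (m/s by segment label)
#'   overriding the velocity model with a piecewise profile along the path
#' @param seed optional RNG seed for the noise; NULL uses the current state
#' @return list with `rec` (an `mea_recording`, channels = path electrodes)
#'   and `truth` (data.frame: neuron, t, n_active, velocity)
#' @export
render_extracellular <- function(spikes, layout, config, path_id = 1,
                                 segment_velocities = NULL, seed = NULL) {
  stopifnot(inherits(spikes, "mea_spiketrains"), inherits(layout, "mea_layout"),
            inherits(config, "sim_config"))
  run <- function() {
    path <- layout$paths[[path_id]]
    cum <- path_cumdist(layout, path)
    n_el <- length(path)
    fs <- config$fs
    dur <- spikes$duration
    n_samp <- as.integer(round(dur * fs))
    trains <- spikes$trains
    if (any(unlist(trains) >= dur)) stop("all spike times must be < duration")

    ap <- data.frame(
      neuron = rep(seq_along(trains), lengths(trains)),
      t = unlist(trains, use.names = FALSE)
    )
    ap <- ap[order(ap$t), , drop = FALSE]

    # co-active axon count: neurons with >= 1 spike within +/- coincidence
    cw <- config$coincidence_ms / 1000
    n_active <- integer(nrow(ap))
    if (nrow(ap)) {
      for (j in seq_along(trains)) {
        tr <- trains[[j]]
        hit <- findInterval(ap$t + cw, tr) - findInterval(ap$t - cw - 1e-12, tr)
        n_active <- n_active + as.integer(hit > 0)
      }
    }
    ap$n_active <- pmax(n_active, 1L)

    tfun <- ap_template(config$template_amp_uv, config$template_width_ms)
    trough <- attr(tfun, "trough_offset")
    width <- attr(tfun, "width")

    if (is.null(segment_velocities)) {
      ap$velocity <- velocity_model(ap$n_active, config$v0, config$coupling)
      delays <- outer(ap$velocity, cum, function(v, d) d * 1e-6 / v)
    } else {
      if (is.null(layout$segments)) stop("layout has no segments")
      seg <- layout$segments[[path_id]]
      ivl_mid <- (cum[-1L] + cum[-length(cum)]) / 2
      lab <- segment_at(seg, ivl_mid)
      if (any(is.na(lab)) || !all(lab %in% names(segment_velocities))) {
        stop("segment_velocities must name every segment crossed by the path")
      }
      v_ivl <- as.numeric(segment_velocities[lab])
      delay_el <- c(0, cumsum(diff(cum) * 1e-6 / v_ivl))
      ap$velocity <- if (n_el > 1L) cum[n_el] * 1e-6 / delay_el[n_el] else NA_real_
      delays <- matrix(delay_el, nrow = nrow(ap), ncol = n_el, byrow = TRUE)
    }

    n_bg <- config$n_background_channels %||% 0
    mat <- matrix(0, nrow = n_el + n_bg, ncol = n_samp)
    half_support <- as.integer(ceiling(width * fs)) + 1L
    for (k in seq_len(nrow(ap))) {
      for (j in seq_len(n_el)) {
        onset <- ap$t[k] + delays[k, j] - trough
        i0 <- max(1L, as.integer(floor(onset * fs)) + 1L)
        i1 <- min(n_samp, i0 + half_support)
        if (i1 < i0) next
        idx <- i0:i1
        mat[j, idx] <- mat[j, idx] + tfun((idx - 1L) / fs - onset)
      }
    }
    if (config$noise_sd > 0) {
      mat <- mat + rnorm(length(mat), 0, config$noise_sd)
    }
    ids <- c(path, if (n_bg > 0) paste0("bg", seq_len(n_bg)))
    rec <- recording(mat, fs = fs, channel_ids = ids,
                     meta = list(simulated = TRUE, seed = seed,
                                 noise_sd = config$noise_sd,
                                 v0 = config$v0, coupling = config$coupling))
    list(rec = rec, truth = ap)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a complete circuit recording
#'
#' Convenience wrapper: builds (or accepts) a layout, simulates spike trains,
#' renders the extracellular recording, and returns everything with ground
#' truth. All randomness derives from `config$seed`.
#'
#' @param config a [sim_config()]
#' @param layout optional `mea_layout`; default is a 5-electrode path at the
#'   standard 200 um pitch
#' @param segment_velocities passed to [render_extracellular()]
#' @return list: `rec`, `spikes`, `truth` (per-AP table), `layout`,
#'   `burst_events`
#' @export
simulate_recording <- function(config, layout = NULL,
                               segment_velocities = NULL) {
  if (is.null(layout)) layout <- build_circuit_layout(5, pitch_um = 200)
  sim <- simulate_spike_trains(config)
  seed_noise <- if (is.null(config$seed)) NULL else config$seed + 1L
  rend <- render_extracellular(sim$spikes, layout, config,
                               segment_velocities = segment_velocities,
                               seed = seed_noise)
  list(rec = rend$rec, spikes = sim$spikes, truth = rend$truth,
       layout = layout, burst_events = sim$truth$burst_events)
}

#' Fraction of microchannel cross-section occupied by axons
#'
#' Treats each axon as a cylinder of the given diameter inside a rectangular
#' microchannel: `n * pi * (d/2)^2 / (h * w)`. For four 1-um axons in a
#' 5 x 30 um channel this is pi/150, about 2% of the channel volume, leaving
#' the bulk of the channel to the medium.
#'
#' @param n_axons number of axons (>= 0)
#' @param axon_diameter_um axon diameter (um)
#' @param channel_height_um channel height (um)
#' @param channel_width_um channel width (um)
#' @return occupancy fraction; warns if it exceeds 1 (non-physical)
#' @export
channel_occupancy_fraction <- function(n_axons, axon_diameter_um = 1,
                                       channel_height_um = 5,
                                       channel_width_um = 30) {
  stopifnot(n_axons >= 0, axon_diameter_um > 0, channel_height_um > 0,
            channel_width_um > 0)
  frac <- n_axons * pi * (axon_diameter_um / 2)^2 /
    (channel_height_um * channel_width_um)
  if (any(frac > 1)) warning("occupancy fraction exceeds 1 (non-physical)")
  frac
}

#' Simulate a stimulation protocol and its evoked responses
#'
#' Electrical default: 30 biphasic pulses (-15 uA then +15 uA, 100 us per
#' phase) with an 1800 ms interpulse interval, so onsets are spaced by the
#' interval plus the 200 us pulse. Optogenetic: pulse trains at a fixed
#' frequency (e.g. 50 ms pulses at 0.5-5 Hz, or 100 ms pulses at 0.5-2 Hz).
#' Ground-truth evoked APs follow each onset at a configurable latency with
#' optional per-pulse latency drift across the train, Gaussian jitter, and a
#' configurable number of APs per pulse at fixed spacing.
#'
#' @param kind `"electrical"` or `"optogenetic"`
#' @param n_pulses number of pulses
#' @param freq_hz optogenetic pulse frequency (Hz)
#' @param pulse_ms optogenetic pulse width (ms)
#' @param ipi_ms electrical interpulse interval (ms)
#' @param phase_us electrical phase duration (us; pulse lasts two phases)
#' @param amp_ua electrical phase amplitude (uA), recorded as the intensity
#'   label
#' @param t_start time of the first onset (s)
#' @param response list of evoked-response parameters: `latency_ms`,
#'   `jitter_ms`, `n_aps` (APs per pulse), `delta_ms` (spacing of subsequent
#'   APs), `drift_ms_per_pulse` (added latency per pulse index, emulating
#'   frequency-dependent slowing), `p_respond` (per-pulse response
#'   probability)
#' @param seed optional RNG seed for jitter/response draws
#' @return list: `stim` (data.frame onset, kind, pulse_ms, intensity) and
#'   `truth` (data.frame pulse, ap, t) of evoked AP times
#' @export
simulate_stim_protocol <- function(kind = c("electrical", "optogenetic"),
                                   n_pulses = 30, freq_hz = 1, pulse_ms = 50,
                                   ipi_ms = 1800, phase_us = 100,
                                   amp_ua = 15, t_start = 0,
                                   response = list(), seed = NULL) {
  kind <- match.arg(kind)
  rp <- modifyList(list(latency_ms = 10, jitter_ms = 0.3, n_aps = 1,
                        delta_ms = 15, drift_ms_per_pulse = 0,
                        p_respond = 1), response)
  if (n_pulses == 0) {
    return(list(stim = data.frame(onset = numeric(0), kind = character(0),
                                  pulse_ms = numeric(0),
                                  intensity = character(0)),
                truth = data.frame(pulse = integer(0), ap = integer(0),
                                   t = numeric(0))))
  }
  if (kind == "electrical") {
    width_ms <- 2 * phase_us / 1000
    onsets <- t_start + (seq_len(n_pulses) - 1L) * (ipi_ms + width_ms) / 1000
    intensity <- sprintf("%+g/%+g uA", -amp_ua, amp_ua)
    pw <- width_ms
  } else {
    period <- 1 / freq_hz
    if (period < pulse_ms / 1000) {
      stop("pulse width ", pulse_ms, " ms exceeds the ", freq_hz,
           " Hz period: pulses would overlap")
    }
    onsets <- t_start + (seq_len(n_pulses) - 1L) * period
    intensity <- sprintf("%g ms @ %g Hz", pulse_ms, freq_hz)
    pw <- pulse_ms
  }
  run <- function() {
    rows <- vector("list", n_pulses)
    for (p in seq_len(n_pulses)) {
      if (runif(1) > rp$p_respond) next
      lat <- rp$latency_ms + rp$drift_ms_per_pulse * (p - 1L) +
        rnorm(1, 0, rp$jitter_ms)
      ts <- onsets[p] + (lat + (seq_len(rp$n_aps) - 1L) * rp$delta_ms) / 1000
      rows[[p]] <- data.frame(pulse = p, ap = seq_len(rp$n_aps), t = ts)
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE))) %||%
      data.frame(pulse = integer(0), ap = integer(0), t = numeric(0))
  }
  truth <- if (is.null(seed)) run() else with_seed(seed, run())
  if (is.null(truth)) {
    truth <- data.frame(pulse = integer(0), ap = integer(0), t = numeric(0))
  }
  list(stim = data.frame(onset = onsets, kind = kind, pulse_ms = pw,
                         intensity = intensity),
       truth = truth)
}
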