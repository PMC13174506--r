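#' Simulation configuration
#'
#' Parameters of the synthetic microchannel experiment. Defaults emulate the
#' study conditions: a 910 um channel of electrodes at 17.5 um pitch (53
#' sites), 10-minute recordings sampled at 20 kHz, propagation at 0.65 mm/ms,
#' an entry-side (proximal-organoid) axon population firing at 2.6 Hz per
#' electrode along the whole channel, and — for directional channels — a
#' distal-organoid population at 5.1 Hz confined to the exit-side half, so
#' the exit quartile totals 7.7 Hz against 2.6 Hz at the entry.
#'
#' @param channel_length_um Channel length (default 910).
#' @param pitch_um Electrode pitch (default 17.5).
#' @param kind `"straight"` or `"directional"`.
#' @param duration_s Recording duration in seconds (default 600).
#' @param sampling_rate_hz Sampling rate for rendered traces (default 20000).
#' @param proximal_rate_hz Per-electrode Poisson rate of the entry-side axon
#'   population (default 2.6). Straight channels split this rate evenly into
#'   two counter-propagating trains so the per-electrode total stays equal.
#' @param distal_rate_hz Rate of the distal-organoid population present only
#'   near the exit of directional channels (default 5.1).
#' @param distal_extent_fraction Fraction of the channel, measured from the
#'   exit end, occupied by distal axons (default 0.5).
#' @param propagation_fraction Fraction of each population's rate carried by
#'   propagating spike sequences shared along the axon (co-occurring events
#'   that pairing can detect); the remainder is independent per-electrode
#'   Poisson background, so per-electrode totals stay at the stated rates
#'   (default 0.4).
#' @param propagation_velocity_um_per_ms,total_latency_ms Exactly one must be
#'   given: conduction velocity, or the total source-to-target transit time
#'   from which velocity is derived (default velocity 650 um/ms = 0.65 mm/ms).
#' @param latency_jitter_ms Gaussian jitter sd added to each downstream
#'   re-emission (default 0).
#' @param detection_dropout_prob Probability a downstream re-emission is
#'   dropped (default 0).
#' @param spike_amplitude_uv Signed trough voltage of rendered spikes
#'   (default -60).
#' @param noise_sd_uv Gaussian noise sd of rendered traces (default 5).
#' @param seed Master seed; every generator is a pure function of
#'   (config, seed).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(channel_length_um = 910, pitch_um = 17.5,
                              kind = c("directional", "straight"),
                              duration_s = 600, sampling_rate_hz = 20000,
                              proximal_rate_hz = 2.6, distal_rate_hz = 5.1,
                              distal_extent_fraction = 0.5,
                              propagation_fraction = 0.4,
                              propagation_velocity_um_per_ms = NULL,
                              total_latency_ms = NULL,
                              latency_jitter_ms = 0,
                              detection_dropout_prob = 0,
                              spike_amplitude_uv = -60, noise_sd_uv = 5,
                              seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(propagation_velocity_um_per_ms) && is.null(total_latency_ms)) {
    propagation_velocity_um_per_ms <- 650
  }
  if (!is.null(propagation_velocity_um_per_ms) && !is.null(total_latency_ms)) {
    abort("give exactly one of `propagation_velocity_um_per_ms` or `total_latency_ms`")
  }
  if (proximal_rate_hz < 0 || distal_rate_hz < 0) abort("rates must be >= 0")
  if (latency_jitter_ms < 0) abort("latency_jitter_ms must be >= 0")
  if (detection_dropout_prob < 0 || detection_dropout_prob > 1) {
    abort("detection_dropout_prob must lie in [0, 1]")
  }
  if (distal_extent_fraction <= 0 || distal_extent_fraction > 1) {
    abort("distal_extent_fraction must lie in (0, 1]")
  }
  if (propagation_fraction < 0 || propagation_fraction > 1) {
    abort("propagation_fraction must lie in [0, 1]")
  }
  structure(
    list(channel_length_um = channel_length_um, pitch_um = pitch_um,
         kind = kind, duration_s = duration_s,
         sampling_rate_hz = sampling_rate_hz,
         proximal_rate_hz = proximal_rate_hz, distal_rate_hz = distal_rate_hz,
         distal_extent_fraction = distal_extent_fraction,
         propagation_fraction = propagation_fraction,
         propagation_velocity_um_per_ms = propagation_velocity_um_per_ms,
         total_latency_ms = total_latency_ms,
         latency_jitter_ms = latency_jitter_ms,
         detection_dropout_prob = detection_dropout_prob,
         spike_amplitude_uv = spike_amplitude_uv, noise_sd_uv = noise_sd_uv,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Ground truth of a simulated dataset
#'
#' @param events Tibble with `electrode_id`, `time_s`, `population`
#'   (`"proximal"` or `"distal"`).
#' @param true_velocity_mm_per_ms True conduction velocity (> 0).
#' @param config Configuration echo (list).
#' @param duration_s Recording duration; all events must fall inside.
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(events, true_velocity_mm_per_ms, config, duration_s) {
  events <- as_tibble(events)
  if (nrow(events) > 0 &&
      any(events$time_s < 0 | events$time_s > duration_s)) {
    abort("ground-truth events must lie within [0, duration_s]")
  }
  if (!is.numeric(true_velocity_mm_per_ms) || true_velocity_mm_per_ms <= 0) {
    abort("true velocity must be > 0")
  }
  structure(list(events = events,
                 true_velocity_mm_per_ms = true_velocity_mm_per_ms,
                 config = config, duration_s = duration_s),
            class = "ground_truth")
}

#' Build a collinear channel electrode layout
#'
#' Places electrodes along the channel axis from entry (axial 0) to exit,
#' one every `pitch_um`; the electrode count is `floor(length/pitch) + 1`
#' and the channel spec endpoints sit on the first and last electrode (so
#' the spec length is the last electrode's axial position).
#'
#' @param length_um Nominal channel length (> 0).
#' @param pitch_um Electrode pitch (> 0, at most `length_um`).
#' @param kind `"straight"` or `"directional"`.
#' @param channel_id Identifier for the spec (default `"ch1"`).
#' @return List with `layout` ([electrode_layout()]) and `spec`
#'   ([microchannel_spec()]).
#' @export
#' @examples
#' ch <- build_channel_layout(910, 17.5, "directional")
#' nrow(ch$layout)  # 53
build_channel_layout <- function(length_um, pitch_um,
                                 kind = c("straight", "directional"),
                                 channel_id = "ch1") {
  kind <- match.arg(kind)
  if (length_um <= 0 || pitch_um <= 0) abort("length and pitch must be > 0")
  n <- floor(length_um / pitch_um + 1e-9) + 1
  if (n < 2) abort("pitch exceeds channel length: fewer than 2 electrodes")
  x <- (seq_len(n) - 1) * pitch_um
  layout <- electrode_layout(seq_len(n), x_um = x, y_um = 0,
                             pitch_um = pitch_um)
  spec <- microchannel_spec(channel_id, kind,
                            entry_xy_um = c(0, 0),
                            exit_xy_um = c(x[n], 0),
                            member_electrode_ids = seq_len(n))
  list(layout = layout, spec = spec)
}

#' Simulate homogeneous Poisson spike trains
#'
#' Independent homogeneous Poisson event times on `[0, duration_s]` per
#' electrode. Each electrode draws from its own deterministic substream of
#' the master seed, so adding electrodes does not reshuffle existing trains.
#'
#' @param layout An [electrode_layout()].
#' @param rate_hz Scalar rate, or a vector with one rate per layout row, or
#'   a named vector keyed by electrode id (Hz, >= 0).
#' @param duration_s Duration in seconds.
#' @param seed Master seed.
#' @param amplitude_uv Amplitude recorded for simulated events (default -60).
#' @param stream_offset Internal offset separating independent populations
#'   drawn from the same master seed.
#' @return A [spike_table()].
#' @export
simulate_poisson_trains <- function(layout, rate_hz, duration_s, seed = 1L,
                                    amplitude_uv = -60, stream_offset = 0L) {
  ids <- layout$electrode_id
  rates <- if (length(rate_hz) == 1) {
    rep(rate_hz, length(ids))
  } else if (!is.null(names(rate_hz))) {
    as.double(rate_hz[as.character(ids)])
  } else {
    if (length(rate_hz) != length(ids)) {
      abort("`rate_hz` must be scalar, named by electrode id, or one per electrode")
    }
    as.double(rate_hz)
  }
  if (any(is.na(rates)) || any(rates < 0)) abort("rates must be >= 0")
  parts <- purrr::map2(ids, rates, function(id, r) {
    if (r == 0) return(NULL)
    with_stream(seed, stream_offset * 100000 + id, {
      n <- rpois(1, r * duration_s)
      if (n == 0) return(NULL)
      tibble(electrode_id = id, time_s = sort(runif(n, 0, duration_s)),
             amplitude_uv = amplitude_uv)
    })
  })
  df <- dplyr::bind_rows(parts)
  if (nrow(df) == 0) {
    df <- tibble(electrode_id = integer(), time_s = double(),
                 amplitude_uv = double())
  }
  spike_table(df, duration_s = duration_s)
}

#' Inject propagating spike events along a channel
#'
#' Re-emits each source event at every electrode along the propagation
#' direction with delay `axial_distance / velocity`, plus optional Gaussian
#' jitter and random dropout of downstream re-emissions. With jitter 0 and
#' dropout 0 the delays are exact and every source event is conserved.
#'
#' @param layout,spec Channel geometry from [build_channel_layout()] (or any
#'   layout/spec pair).
#' @param source_times Source event times in seconds (at the propagation
#'   origin: the entry for `direction = "forward"`, the exit otherwise).
#' @param duration_s Recording duration; re-emissions landing outside
#'   `[0, duration_s]` are dropped.
#' @param velocity_um_per_ms,total_latency_ms Exactly one: conduction
#'   velocity, or total entry-to-exit transit time.
#' @param jitter_ms Gaussian jitter sd (ms) on downstream delays.
#' @param dropout_prob Probability of dropping each downstream re-emission.
#' @param direction `"forward"` (entry to exit) or `"backward"`. Injecting
#'   backward through a directional spec is allowed (it emulates
#'   prohibitive-side activity) and is the caller's responsibility to label.
#' @param electrode_ids Optional subset of member electrodes reached by the
#'   propagating axons (default: all members).
#' @param seed Master seed for jitter/dropout draws.
#' @param amplitude_uv Amplitude recorded for events (default -60).
#' @return A [spike_table()] (column `distance_um` retained for inspection).
#' @export
inject_propagating_events <- function(layout, spec, source_times, duration_s,
                                      velocity_um_per_ms = NULL,
                                      total_latency_ms = NULL,
                                      jitter_ms = 0, dropout_prob = 0,
                                      direction = c("forward", "backward"),
                                      electrode_ids = NULL, seed = 1L,
                                      amplitude_uv = -60) {
  direction <- match.arg(direction)
  if (is.null(velocity_um_per_ms) == is.null(total_latency_ms)) {
    abort("give exactly one of `velocity_um_per_ms` or `total_latency_ms`")
  }
  if (is.null(velocity_um_per_ms)) {
    velocity_um_per_ms <- spec$length_um / total_latency_ms
  }
  if (velocity_um_per_ms <= 0) abort("velocity must be > 0")
  if (any(source_times < 0 | source_times > duration_s)) {
    abort("source times must lie within [0, duration_s]")
  }
  source_times <- sort(source_times)
  amap <- axial_map(layout, spec)
  members <- amap[amap$electrode_id %in% spec$member_electrode_ids, ]
  if (!is.null(electrode_ids)) {
    members <- members[members$electrode_id %in% electrode_ids, ]
  }
  dist_um <- if (direction == "forward") {
    members$axial_um
  } else {
    spec$length_um - members$axial_um
  }
  keep <- dist_um >= -1e-9
  members <- members[keep, , drop = FALSE]
  dist_um <- pmax(dist_um[keep], 0)
  n_src <- length(source_times)
  parts <- purrr::map2(members$electrode_id, dist_um, function(id, d) {
    delay_s <- d / velocity_um_per_ms / 1000
    t <- source_times + delay_s
    if (d > 0) {
      with_stream(seed, id, {
        if (jitter_ms > 0) t <- t + rnorm(n_src, 0, jitter_ms / 1000)
        if (dropout_prob > 0) t <- t[runif(n_src) >= dropout_prob]
      })
    }
    t <- t[t >= 0 & t <= duration_s]
    if (length(t) == 0) return(NULL)
    tibble(electrode_id = id, time_s = t, amplitude_uv = amplitude_uv,
           distance_um = d)
  })
  df <- dplyr::bind_rows(parts)
  if (nrow(df) == 0) {
    df <- tibble(electrode_id = integer(), time_s = double(),
                 amplitude_uv = double(), distance_um = double())
  }
  spike_table(df, duration_s = duration_s)
}

spike_template <- function(sampling_rate_hz, support_s = 0.001) {
  n <- round(sampling_rate_hz * support_s) + 1
  if (n < 3) abort("sampling rate too low for the 1 ms spike template")
  tt <- (seq_len(n) - 1) / (n - 1)
  w <- -exp(-((tt - 0.3) / 0.12)^2) + 0.35 * exp(-((tt - 0.7) / 0.15)^2)
  w <- w / abs(min(w))
  list(shape = w, trough = which.min(w))
}

#' Render a raw recording from a spike table
#'
#' Adds a fixed biphasic extracellular template (1 ms support, trough at the
#' event's signed amplitude) at the sample nearest each event time, on top of
#' independent Gaussian noise per sample. Overlapping events on one electrode
#' sum.
#'
#' @param spikes A [spike_table()].
#' @param layout An [electrode_layout()] covering every spiking electrode.
#' @param sampling_rate_hz Sampling rate (>= 2 kHz for the 1 ms template).
#' @param noise_sd_uv Gaussian noise sd in uV (default 5).
#' @param seed Master seed for the noise streams.
#' @return An [mea_recording()].
#' @export
render_raw_recording <- function(spikes, layout, sampling_rate_hz,
                                 noise_sd_uv = 5, seed = 1L) {
  duration_s <- spike_duration(spikes)
  n_samples <- round(duration_s * sampling_rate_hz)
  tpl <- spike_template(sampling_rate_hz)
  half_lo <- tpl$trough - 1
  half_hi <- length(tpl$shape) - tpl$trough
  signals <- matrix(0, nrow = nrow(layout), ncol = n_samples)
  for (i in seq_len(nrow(layout))) {
    id <- layout$electrode_id[i]
    if (noise_sd_uv > 0) {
      signals[i, ] <- with_stream(seed, 50000 + id,
                                  rnorm(n_samples, 0, noise_sd_uv))
    }
    ev <- spikes[spikes$electrode_id == id, ]
    if (nrow(ev) == 0) next
    centers <- round(ev$time_s * sampling_rate_hz) + 1
    for (k in seq_len(nrow(ev))) {
      idx <- (centers[k] - half_lo):(centers[k] + half_hi)
      ok <- idx >= 1 & idx <= n_samples
      signals[i, idx[ok]] <- signals[i, idx[ok]] -
        ev$amplitude_uv[k] * tpl$shape[ok]
    }
  }
  mea_recording(layout, signals, sampling_rate_hz)
}

#' Simulate a full microchannel dataset
#'
#' Builds the channel geometry and populations the study conditions imply.
#' Each axon population contributes an independent per-electrode Poisson
#' background plus propagating spike sequences shared along the channel
#' (fraction `propagation_fraction` of its rate), so per-electrode totals
#' stay at the stated rates. Straight channels carry the proximal population
#' symmetrically, with propagating trains in both directions at equal rates.
#' Directional channels carry the proximal population (forward propagation)
#' along the whole channel plus a distal-organoid population at
#' `distal_rate_hz` confined to the exit-side `distal_extent_fraction`,
#' propagating backward within that extent — the accumulation of
#' non-permissive-side neurites at permissive channel exits. The exit
#' quartile thus totals `proximal_rate_hz + distal_rate_hz` against
#' `proximal_rate_hz` at the entry.
#'
#' @param cfg A [simulation_config()].
#' @param render_raw Render dense traces as well? Off by default: at the
#'   default 600 s x 20 kHz x 53 electrodes a trace matrix is far larger than
#'   the spike-level representation, so rendering is reserved for short
#'   recordings that exercise the detector.
#' @return List with `recording` (or `NULL`), `spikes`, `spec`, `layout`,
#'   `ground_truth`.
#' @export
#' @examples
#' sim <- simulate_channel_dataset(simulation_config(kind = "straight",
#'   duration_s = 30, proximal_rate_hz = 2, seed = 42))
#' nrow(sim$spikes)
simulate_channel_dataset <- function(cfg, render_raw = FALSE) {
  if (!inherits(cfg, "simulation_config")) abort("`cfg` must be a simulation_config")
  ch <- build_channel_layout(cfg$channel_length_um, cfg$pitch_um, cfg$kind)
  layout <- ch$layout
  spec <- ch$spec
  v <- cfg$propagation_velocity_um_per_ms %||%
    (spec$length_um / cfg$total_latency_ms)
  seed <- cfg$seed

  rho <- cfg$propagation_fraction

  inject <- function(rate, direction, electrode_ids, stream, label) {
    src <- simulate_poisson_trains(
      electrode_layout(0L, 0, 0, pitch_um = cfg$pitch_um), rate,
      cfg$duration_s, seed = substream_seed(seed, stream),
      amplitude_uv = cfg$spike_amplitude_uv
    )
    ev <- inject_propagating_events(
      layout, spec, src$time_s, cfg$duration_s,
      velocity_um_per_ms = v, jitter_ms = cfg$latency_jitter_ms,
      dropout_prob = cfg$detection_dropout_prob, direction = direction,
      electrode_ids = electrode_ids,
      seed = substream_seed(seed, stream + 1),
      amplitude_uv = cfg$spike_amplitude_uv
    )
    ev$population <- if (nrow(ev) > 0) label else character(0)
    ev
  }
  background <- function(rate, electrode_ids, stream, label) {
    lay <- layout
    if (!is.null(electrode_ids)) {
      lay <- layout[layout$electrode_id %in% electrode_ids, ]
    }
    ev <- simulate_poisson_trains(lay, rate, cfg$duration_s,
                                  seed = substream_seed(seed, stream),
                                  amplitude_uv = cfg$spike_amplitude_uv)
    ev$population <- if (nrow(ev) > 0) label else character(0)
    ev
  }

  if (cfg$kind == "straight") {
    p <- cfg$proximal_rate_hz
    events <- dplyr::bind_rows(
      background((1 - rho) * p, NULL, 41, "proximal"),
      inject(rho * p / 2, "forward", NULL, 11, "proximal"),
      inject(rho * p / 2, "backward", NULL, 21, "distal")
    )
  } else {
    amap <- axial_map(layout, spec)
    distal_ids <- amap$electrode_id[
      amap$axial_fraction >= 1 - cfg$distal_extent_fraction - 1e-9]
    events <- dplyr::bind_rows(
      background((1 - rho) * cfg$proximal_rate_hz, NULL, 41, "proximal"),
      inject(rho * cfg$proximal_rate_hz, "forward", NULL, 11, "proximal"),
      background((1 - rho) * cfg$distal_rate_hz, distal_ids, 51, "distal"),
      inject(rho * cfg$distal_rate_hz, "backward", distal_ids, 21, "distal")
    )
  }
  events$distance_um <- NULL
  spikes <- spike_table(events, duration_s = cfg$duration_s)
  gt <- ground_truth(
    spikes[, c("electrode_id", "time_s", "population")],
    true_velocity_mm_per_ms = v / 1000,
    config = unclass(cfg), duration_s = cfg$duration_s
  )
  spikes$population <- NULL
  recording <- NULL
  if (render_raw) {
    recording <- render_raw_recording(spikes, layout, cfg$sampling_rate_hz,
                                      noise_sd_uv = cfg$noise_sd_uv,
                                      seed = substream_seed(seed, 31))
  }
  list(recording = recording, spikes = spikes, spec = spec, layout = layout,
       ground_truth = gt)
}

#' Simulate neurite tracks and axial intensity profiles
#'
#' Each track is a cumulative sum of non-negative hourly axial steps
#' (Gaussian, truncated at zero), capped at the channel length — the
#' growth-cone dynamics observed in permissive (fast) versus prohibitive
#' (slow, stalling) channel orientations. The intensity profile counts, at
#' each axial position, the tracks whose tip has passed it, scaled to
#' arbitrary fluorescence units.
#'
#' @param n_tracks_per_condition Named integer vector, e.g.
#'   `c(permissive = 97, prohibitive = 90)` (the study's track counts).
#' @param mean_step_um_per_hr Named mean hourly step per condition (default
#'   `c(permissive = 11.4, prohibitive = 2.9)`).
#' @param step_sd_um_per_hr Named step sd per condition (default
#'   `c(permissive = 4, prohibitive = 1)`: small enough relative to the means
#'   that zero-truncation leaves them essentially unbiased).
#' @param hours Number of hourly observations after seeding (default 16).
#' @param channel_length_um Channel length cap (default 900).
#' @param profile_step_um Axial sampling step of the intensity profile.
#' @param intensity_scale Arbitrary fluorescence units per track.
#' @param seed Master seed.
#' @return List with `tracks` (tibble: `track_id`, `condition`, `hour`,
#'   `axial_position_um`) and `profiles` (tibble: `channel_id`, `axial_um`,
#'   `intensity`).
#' @export
simulate_neurite_dataset <- function(n_tracks_per_condition =
                                       c(permissive = 97, prohibitive = 90),
                                     mean_step_um_per_hr =
                                       c(permissive = 11.4, prohibitive = 2.9),
                                     step_sd_um_per_hr =
                                       c(permissive = 4, prohibitive = 1),
                                     hours = 16, channel_length_um = 900,
                                     profile_step_um = 5,
                                     intensity_scale = 20, seed = 1L) {
  if (hours < 1) abort("`hours` must be >= 1")
  if (any(step_sd_um_per_hr < 0)) abort("step sds must be >= 0")
  conds <- names(n_tracks_per_condition)
  if (is.null(conds) || !all(conds %in% names(mean_step_um_per_hr))) {
    abort("condition names must match across the parameter vectors")
  }
  tracks <- purrr::imap(as.list(n_tracks_per_condition), function(n, cond) {
    mu <- mean_step_um_per_hr[[cond]]
    sdv <- step_sd_um_per_hr[[cond]]
    ci <- match(cond, conds)
    purrr::map(seq_len(n), function(k) {
      steps <- with_stream(seed, ci * 1000000 + k,
                           pmax(0, rnorm(hours, mu, sdv)))
      pos <- pmin(cumsum(steps), channel_length_um)
      tibble(track_id = paste0(cond, "_", k), condition = cond,
             hour = 0:hours, axial_position_um = c(0, pos))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  final <- tracks |>
    dplyr::group_by(.data$condition, .data$track_id) |>
    dplyr::summarise(tip = max(.data$axial_position_um), .groups = "drop")
  positions <- seq(0, channel_length_um, by = profile_step_um)
  profiles <- purrr::map(conds, function(cond) {
    tips <- final$tip[final$condition == cond]
    tibble(channel_id = cond, axial_um = positions,
           intensity = intensity_scale *
             vapply(positions, function(p) sum(tips >= p), double(1)))
  }) |> dplyr::bind_rows()
  list(tracks = tracks, profiles = profiles)
}
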