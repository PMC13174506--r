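#' Electrode layout table
#'
#' A tibble of recording-site positions. High-density arrays expose thousands
#' of sites; an analysis layout is the subset routed to one or more
#' microchannels.
#'
#' @param electrode_id Integer electrode labels (unique).
#' @param x_um,y_um Planar positions in micrometres (finite).
#' @param pitch_um Nominal inter-electrode spacing in micrometres (metadata,
#'   stored as an attribute).
#' @return A tibble of class `electrode_layout` with columns
#'   `electrode_id`, `x_um`, `y_um` and attribute `pitch_um`.
#' @export
#' @examples
#' electrode_layout(1:3, x_um = c(0, 17.5, 35), y_um = 0)
electrode_layout <- function(electrode_id, x_um, y_um, pitch_um = 17.5) {
  electrode_id <- as.integer(electrode_id)
  if (anyDuplicated(electrode_id) > 0) abort("electrode ids must be unique")
  df <- tibble(electrode_id = electrode_id,
               x_um = as.double(x_um), y_um = as.double(y_um))
  if (any(!is.finite(df$x_um)) || any(!is.finite(df$y_um))) {
    abort("electrode positions must be finite")
  }
  if (!is.numeric(pitch_um) || pitch_um <= 0) abort("pitch_um must be > 0")
  attr(df, "pitch_um") <- as.double(pitch_um)
  class(df) <- c("electrode_layout", class(df))
  df
}

#' @rdname electrode_layout
#' @param layout An `electrode_layout`.
#' @export
layout_pitch <- function(layout) attr(layout, "pitch_um")

#' Microchannel geometry specification
#'
#' Describes one microchannel: its endpoints (the entry is the
#' proximal-organoid side; for directional channels entry to exit is the
#' permissive growth direction), length, kind, and member electrodes.
#'
#' @param channel_id Channel identifier (scalar).
#' @param kind `"straight"` or `"directional"`.
#' @param entry_xy_um,exit_xy_um Numeric length-2 endpoint coordinates (um).
#' @param member_electrode_ids Integer ids of electrodes inside the channel
#'   (at least 2).
#' @param length_um Optional declared length; must equal the Euclidean
#'   endpoint distance within 1e-6 um. Computed when omitted.
#' @return A `microchannel_spec` list.
#' @export
#' @examples
#' microchannel_spec("ch1", "directional", c(0, 0), c(910, 0), 1:53)
microchannel_spec <- function(channel_id, kind, entry_xy_um, exit_xy_um,
                              member_electrode_ids, length_um = NULL) {
  kind <- match.arg(kind, c("straight", "directional"))
  entry_xy_um <- as.double(entry_xy_um)
  exit_xy_um <- as.double(exit_xy_um)
  if (length(entry_xy_um) != 2 || length(exit_xy_um) != 2 ||
      any(!is.finite(c(entry_xy_um, exit_xy_um)))) {
    abort("channel endpoints must be finite length-2 coordinates")
  }
  dist <- sqrt(sum((exit_xy_um - entry_xy_um)^2))
  if (is.null(length_um)) {
    length_um <- dist
  } else if (abs(length_um - dist) > 1e-6) {
    abort("length_um does not match the endpoint distance (tolerance 1e-6 um)")
  }
  member_electrode_ids <- as.integer(member_electrode_ids)
  if (length(member_electrode_ids) < 2) {
    abort("a microchannel needs at least 2 member electrodes")
  }
  structure(
    list(channel_id = channel_id, kind = kind,
         entry_xy_um = entry_xy_um, exit_xy_um = exit_xy_um,
         length_um = as.double(length_um),
         member_electrode_ids = member_electrode_ids),
    class = "microchannel_spec"
  )
}

#' @export
print.microchannel_spec <- function(x, ...) {
  cat(sprintf("<microchannel_spec> %s (%s), %.1f um, %d electrodes\n",
              x$channel_id, x$kind, x$length_um,
              length(x$member_electrode_ids)))
  invisible(x)
}

#' Spike table
#'
#' The pipeline's central exchange format: discrete detected or simulated
#' events, one row per spike, in canonical order (electrode, then time; ties
#' in time broken by amplitude descending).
#'
#' @param x Data frame with columns `electrode_id`, `time_s`, `amplitude_uv`
#'   (extra columns such as a ground-truth `population` label are kept).
#' @param duration_s Recording duration in seconds; all times must lie in
#'   `[0, duration_s]`.
#' @return A tibble of class `spike_table` with attribute `duration_s`.
#' @export
#' @examples
#' spike_table(data.frame(electrode_id = 1L, time_s = 0.5,
#'                        amplitude_uv = -60), duration_s = 10)
spike_table <- function(x, duration_s) {
  need <- c("electrode_id", "time_s", "amplitude_uv")
  if (!all(need %in% names(x))) {
    abort(paste("spike table needs columns:", paste(need, collapse = ", ")))
  }
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0) {
    abort("duration_s must be a positive scalar")
  }
  df <- as_tibble(x)
  df$electrode_id <- as.integer(df$electrode_id)
  df$time_s <- as.double(df$time_s)
  df$amplitude_uv <- as.double(df$amplitude_uv)
  if (nrow(df) > 0) {
    if (any(df$time_s < 0 | df$time_s > duration_s)) {
      abort("spike times must lie within [0, duration_s]")
    }
    df <- df[order(df$electrode_id, df$time_s, -df$amplitude_uv), , drop = FALSE]
  }
  attr(df, "duration_s") <- as.double(duration_s)
  class(df) <- unique(c("spike_table", class(df)))
  df
}

#' @rdname spike_table
#' @param spikes A `spike_table`.
#' @export
spike_duration <- function(spikes) {
  d <- attr(spikes, "duration_s")
  if (is.null(d)) abort("not a spike_table: missing duration_s attribute")
  d
}

#' Raw multi-electrode recording
#'
#' Dense per-electrode voltage traces plus the layout they were recorded on.
#'
#' @param layout An [electrode_layout()].
#' @param signals Numeric matrix, one row per layout electrode (same order),
#'   one column per sample, in microvolts.
#' @param sampling_rate_hz Samples per second (> 0).
#' @return An `mea_recording` list with fields `layout`, `signals`,
#'   `sampling_rate_hz`, `duration_s`.
#' @export
mea_recording <- function(layout, signals, sampling_rate_hz) {
  if (!inherits(layout, "electrode_layout")) abort("`layout` must be an electrode_layout")
  signals <- as.matrix(signals)
  if (nrow(signals) != nrow(layout)) {
    abort("`signals` must have one row per layout electrode")
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    abort("sampling_rate_hz must be > 0")
  }
  structure(
    list(layout = layout, signals = signals,
         sampling_rate_hz = as.double(sampling_rate_hz),
         duration_s = ncol(signals) / sampling_rate_hz),
    class = "mea_recording"
  )
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording> %d electrodes x %d samples @ %g Hz (%.3f s)\n",
              nrow(x$signals), ncol(x$signals), x$sampling_rate_hz,
              x$duration_s))
  invisible(x)
}
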