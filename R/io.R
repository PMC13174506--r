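FORMAT_VERSION <- "axonflux/1"

#' Write and read the recording container
#'
#' Recordings travel as HDF5: datasets `/signals` (electrodes x samples,
#' single precision, uV), `/electrode_ids`, `/positions_um` (n x 2), with
#' root attributes `sampling_rate_hz`, `pitch_um` and `format_version`.
#' Simulated ground truth, when present, is stored under `/ground_truth` so
#' downstream checks can reload it alongside the traces.
#'
#' @param recording An [mea_recording()].
#' @param path Output `.h5` path (overwritten).
#' @param ground_truth Optional [ground_truth()] object to embed.
#' @return `path`, invisibly.
#' @export
write_recording_h5 <- function(recording, path, ground_truth = NULL) {
  if (!inherits(recording, "mea_recording")) abort("`recording` must be an mea_recording")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  dims <- dim(recording$signals)
  rhdf5::h5createDataset(path, "signals", dims = dims,
                         H5type = "H5T_IEEE_F32LE", chunk = dims)
  rhdf5::h5write(recording$signals, path, "signals")
  rhdf5::h5write(recording$layout$electrode_id, path, "electrode_ids")
  rhdf5::h5write(cbind(recording$layout$x_um, recording$layout$y_um),
                 path, "positions_um")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(recording$sampling_rate_hz, fid, "sampling_rate_hz")
  rhdf5::h5writeAttribute(layout_pitch(recording$layout), fid, "pitch_um")
  rhdf5::h5writeAttribute(FORMAT_VERSION, fid, "format_version")
  rhdf5::H5Fclose(fid)
  if (!is.null(ground_truth)) {
    rhdf5::h5createGroup(path, "ground_truth")
    rhdf5::h5write(ground_truth$events$electrode_id, path, "ground_truth/electrode_id")
    rhdf5::h5write(ground_truth$events$time_s, path, "ground_truth/time_s")
    rhdf5::h5write(ground_truth$events$population, path, "ground_truth/population")
    rhdf5::h5write(ground_truth$true_velocity_mm_per_ms, path,
                   "ground_truth/true_velocity_mm_per_ms")
    rhdf5::h5write(as.character(jsonlite::toJSON(ground_truth$config,
                                                 auto_unbox = TRUE,
                                                 null = "null")),
                   path, "ground_truth/config_json")
  }
  invisible(path)
}

#' @rdname write_recording_h5
#' @return For `read_recording_h5()`: a list with elements `recording` and
#'   `ground_truth` (`NULL` when the file carries none).
#' @export
read_recording_h5 <- function(path) {
  if (!file.exists(path)) abort(paste("no such recording file:", path))
  version <- tryCatch(rhdf5::h5readAttributes(path, "/")$format_version,
                      error = function(e) NULL)
  if (is.null(version) || !identical(as.character(version), FORMAT_VERSION)) {
    abort(paste0("unsupported recording format version: ",
                 version %||% "<missing>"))
  }
  at <- rhdf5::h5readAttributes(path, "/")
  ids <- as.integer(rhdf5::h5read(path, "electrode_ids"))
  if (anyDuplicated(ids) > 0) abort("duplicate electrode ids in recording file")
  pos <- rhdf5::h5read(path, "positions_um")
  layout <- electrode_layout(ids, pos[, 1], pos[, 2],
                             pitch_um = as.double(at$pitch_um))
  signals <- rhdf5::h5read(path, "signals")
  rec <- mea_recording(layout, signals, as.double(at$sampling_rate_hz))
  gt <- NULL
  if ("ground_truth" %in% rhdf5::h5ls(path)$name) {
    events <- tibble(
      electrode_id = as.integer(rhdf5::h5read(path, "ground_truth/electrode_id")),
      time_s = as.double(rhdf5::h5read(path, "ground_truth/time_s")),
      population = as.character(rhdf5::h5read(path, "ground_truth/population"))
    )
    gt <- ground_truth(
      events,
      true_velocity_mm_per_ms =
        as.double(rhdf5::h5read(path, "ground_truth/true_velocity_mm_per_ms")),
      config = jsonlite::fromJSON(
        as.character(rhdf5::h5read(path, "ground_truth/config_json"))),
      duration_s = rec$duration_s
    )
  }
  list(recording = rec, ground_truth = gt)
}

#' Write and read spike tables as CSV
#'
#' Plain CSV with header `electrode_id,time_s,amplitude_uv`, preceded by
#' comment lines carrying the format version and the recording duration
#' (`# duration_s=<float>`). Rows are written in canonical (electrode, time)
#' order; loading preserves every record.
#'
#' @param spikes A [spike_table()].
#' @param path CSV path.
#' @return `path` invisibly; `read_spike_csv()` returns the `spike_table`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' st <- spike_table(data.frame(electrode_id = c(2L, 1L),
#'                              time_s = c(0.5, 1), amplitude_uv = -60),
#'                   duration_s = 10)
#' write_spike_csv(st, f)
#' read_spike_csv(f)
write_spike_csv <- function(spikes, path) {
  d <- spike_duration(spikes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# format_version=", FORMAT_VERSION),
               sprintf("# duration_s=%.17g", d),
               "electrode_id,time_s,amplitude_uv"), con)
  if (nrow(spikes) > 0) {
    writeLines(sprintf("%d,%.17g,%.17g", spikes$electrode_id,
                       spikes$time_s, spikes$amplitude_uv), con)
  }
  invisible(path)
}

#' @rdname write_spike_csv
#' @export
read_spike_csv <- function(path) {
  if (!file.exists(path)) abort(paste("no such spike file:", path))
  lines <- readLines(path)
  comments <- grep("^#", lines, value = TRUE)
  version <- sub("^# format_version=", "",
                 grep("^# format_version=", comments, value = TRUE))
  if (length(version) != 1 || version != FORMAT_VERSION) {
    abort("unsupported spike table format version")
  }
  dur_line <- grep("^# duration_s=", comments, value = TRUE)
  if (length(dur_line) != 1) abort("spike file missing `# duration_s=` line")
  duration_s <- as.double(sub("^# duration_s=", "", dur_line))
  body <- lines[!grepl("^#", lines)]
  header <- body[1]
  if (!identical(header, "electrode_id,time_s,amplitude_uv")) {
    abort("spike file header must be `electrode_id,time_s,amplitude_uv`")
  }
  if (length(body) > 1) {
    df <- utils::read.csv(text = body, colClasses =
                            c("integer", "numeric", "numeric"))
  } else {
    df <- data.frame(electrode_id = integer(), time_s = double(),
                     amplitude_uv = double())
  }
  spike_table(df, duration_s = duration_s)
}

#' Write and read microchannel specifications
#'
#' Channel specs are stored as YAML (or JSON, by file extension) with keys
#' exactly matching the `microchannel_spec` fields plus a format version.
#'
#' @param channels A `microchannel_spec` or list of them.
#' @param path Output path ending in `.yaml`, `.yml`, or `.json`.
#' @return `path` invisibly; `read_channel_specs()` returns a list of
#'   `microchannel_spec`.
#' @export
write_channel_specs <- function(channels, path) {
  if (inherits(channels, "microchannel_spec")) channels <- list(channels)
  payload <- list(
    format_version = FORMAT_VERSION,
    channels = lapply(channels, function(ch) {
      list(channel_id = ch$channel_id, kind = ch$kind,
           entry_xy_um = ch$entry_xy_um, exit_xy_um = ch$exit_xy_um,
           length_um = ch$length_um,
           member_electrode_ids = ch$member_electrode_ids)
    })
  )
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(payload, path, precision = 15)
  }
  invisible(path)
}

#' @rdname write_channel_specs
#' @export
read_channel_specs <- function(path) {
  if (!file.exists(path)) abort(paste("no such channel spec file:", path))
  payload <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!identical(payload$format_version, FORMAT_VERSION)) {
    abort("unsupported channel spec format version")
  }
  lapply(payload$channels, function(ch) {
    microchannel_spec(ch$channel_id, ch$kind,
                      unlist(ch$entry_xy_um), unlist(ch$exit_xy_um),
                      unlist(ch$member_electrode_ids),
                      length_um = ch$length_um)
  })
}

#' Save or load a dataset bundle
#'
#' A bundle is a directory holding whichever artifacts a run produced:
#' `recording.h5` (raw traces, optional ground truth), `spikes.csv`, and
#' `channels.yaml`. At least one of recording/spikes must be present.
#' `load_bundle(save_bundle(...))` reproduces spike tables and channel specs
#' bit-exactly; signals round-trip within single-precision rounding.
#'
#' @param path Bundle directory (created if needed).
#' @param recording Optional [mea_recording()].
#' @param spikes Optional [spike_table()].
#' @param channels List of [microchannel_spec()] (may be empty).
#' @param ground_truth Optional [ground_truth()], stored inside the
#'   recording container.
#' @return `save_bundle()`: `path` invisibly. `load_bundle()`: list with
#'   `recording`, `spikes`, `channels`, `ground_truth` (absent pieces are
#'   `NULL` / empty list).
#' @export
save_bundle <- function(path, recording = NULL, spikes = NULL,
                        channels = list(), ground_truth = NULL) {
  if (is.null(recording) && is.null(spikes)) {
    abort("a bundle needs at least one of `recording` or `spikes`")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(recording)) {
    write_recording_h5(recording, file.path(path, "recording.h5"),
                       ground_truth = ground_truth)
  }
  if (!is.null(spikes)) write_spike_csv(spikes, file.path(path, "spikes.csv"))
  if (length(channels) > 0 || inherits(channels, "microchannel_spec")) {
    write_channel_specs(channels, file.path(path, "channels.yaml"))
  }
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  if (!dir.exists(path)) abort(paste("no such bundle directory:", path))
  out <- list(recording = NULL, spikes = NULL, channels = list(),
              ground_truth = NULL)
  rec_path <- file.path(path, "recording.h5")
  if (file.exists(rec_path)) {
    loaded <- read_recording_h5(rec_path)
    out$recording <- loaded$recording
    out$ground_truth <- loaded$ground_truth
  }
  sp_path <- file.path(path, "spikes.csv")
  if (file.exists(sp_path)) out$spikes <- read_spike_csv(sp_path)
  ch_path <- file.path(path, "channels.yaml")
  if (file.exists(ch_path)) out$channels <- read_channel_specs(ch_path)
  out
}
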