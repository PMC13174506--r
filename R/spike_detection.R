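#' Baseline scale of a voltage trace
#'
#' Plain root-mean-square over the full trace (default), or the robust
#' median-absolute-deviation estimate MAD / 0.6745 which is insensitive to
#' the spikes themselves.
#'
#' @param trace Numeric voltage samples (uV), at least one.
#' @param method `"rms"` or `"mad"`.
#' @return Scalar baseline estimate in uV.
#' @export
#' @examples
#' estimate_rms(sin(seq(0, 2 * pi, length.out = 1000)))  # ~ 1/sqrt(2)
estimate_rms <- function(trace, method = c("rms", "mad")) {
  method <- match.arg(method)
  if (length(trace) < 1) abort("empty trace")
  if (any(!is.finite(trace))) abort("trace contains non-finite samples")
  if (method == "rms") {
    sqrt(mean(trace^2))
  } else {
    median(abs(trace - median(trace))) / 0.6745
  }
}

#' Threshold spike detection on one trace
#'
#' Finds local extrema of `|v|` strictly exceeding the threshold. Within any
#' contiguous supra-threshold run only the largest-magnitude sample is
#' reported; the event time is that sample index over the sampling rate and
#' the amplitude is the signed voltage there.
#'
#' @param trace Numeric voltage samples (uV).
#' @param sampling_rate_hz Samples per second.
#' @param threshold_uv Detection threshold (> 0), typically
#'   `rms_threshold_multiple * estimate_rms(trace)`.
#' @return Tibble with `time_s`, `amplitude_uv`, one row per event.
#' @export
detect_spikes <- function(trace, sampling_rate_hz, threshold_uv) {
  if (threshold_uv <= 0) abort("threshold must be > 0")
  if (any(!is.finite(trace))) abort("trace contains non-finite samples")
  over <- abs(trace) > threshold_uv
  if (!any(over)) return(tibble(time_s = double(), amplitude_uv = double()))
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  idx <- vapply(runs, function(k) {
    span <- starts[k]:ends[k]
    span[which.max(abs(trace[span]))]
  }, integer(1))
  tibble(time_s = (idx - 1) / sampling_rate_hz,
         amplitude_uv = trace[idx])
}

#' Refractory (inter-spike-interval) filter
#'
#' Greedy earliest-first: keep the first event, then discard any event closer
#' than `min_isi_s` to the last kept event. All consecutive gaps in the
#' output are at least `min_isi_s`.
#'
#' @param times Sorted ascending event times (s).
#' @param min_isi_s Minimum allowed inter-spike interval (default 0.001 s).
#' @return Filtered times (subset of the input, same order).
#' @export
#' @examples
#' apply_isi_filter(c(0, 0.0009, 0.0018), 0.001)  # drops the middle event
apply_isi_filter <- function(times, min_isi_s = 0.001) {
  if (is.unsorted(times)) abort("`times` must be sorted ascending")
  n <- length(times)
  if (n <= 1) return(times)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- times[1]
  for (i in 2:n) {
    if (times[i] - last >= min_isi_s) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Firing rate
#'
#' @param times Event times (only the count is used).
#' @param duration_s Recording duration (> 0).
#' @return Rate in Hz: `length(times) / duration_s`.
#' @export
firing_rate <- function(times, duration_s) {
  if (duration_s <= 0) abort("duration must be > 0")
  length(times) / duration_s
}

#' Detect spikes across a whole recording
#'
#' Per electrode: estimates the baseline, thresholds at
#' `rms_threshold_multiple` times it, detects per-run extrema, then removes
#' inter-spike intervals shorter than `isi_min_s` (greedy earliest-first).
#'
#' @param recording An [mea_recording()].
#' @param cfg An [analysis_config()].
#' @return A `detection_result`: list with `spikes` (a [spike_table()]) and
#'   `summary`, a tibble per electrode of `rms_uv`, `threshold_uv`,
#'   `n_detected`, `n_kept`.
#' @export
detect_recording <- function(recording, cfg = analysis_config()) {
  cfg <- validate_config(cfg)
  layout <- recording$layout
  parts <- vector("list", nrow(layout))
  summ <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    trace <- recording$signals[i, ]
    rms <- estimate_rms(trace, method = cfg$rms_method)
    thr <- cfg$rms_threshold_multiple * rms
    ev <- if (thr > 0) {
      detect_spikes(trace, recording$sampling_rate_hz, thr)
    } else {
      tibble(time_s = double(), amplitude_uv = double())
    }
    kept_times <- apply_isi_filter(ev$time_s, cfg$isi_min_s)
    kept <- ev[ev$time_s %in% kept_times, , drop = FALSE]
    parts[[i]] <- tibble(electrode_id = layout$electrode_id[i],
                         time_s = kept$time_s,
                         amplitude_uv = kept$amplitude_uv)
    summ[[i]] <- tibble(electrode_id = layout$electrode_id[i],
                        rms_uv = rms, threshold_uv = thr,
                        n_detected = nrow(ev), n_kept = nrow(kept))
  }
  spikes <- spike_table(dplyr::bind_rows(parts),
                        duration_s = recording$duration_s)
  structure(list(spikes = spikes, summary = dplyr::bind_rows(summ)),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %d events on %d electrodes (%.0f detected pre-ISI)\n",
              nrow(x$spikes), nrow(x$summary), sum(x$summary$n_detected)))
  invisible(x)
}
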