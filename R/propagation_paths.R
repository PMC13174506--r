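times_of <- function(spikes, electrode_id) {
  spikes$time_s[spikes$electrode_id == electrode_id]
}

#' Pair source and target spike events
#'
#' Scans source events in time order and pairs each with the earliest unused
#' target event whose latency `t_target - t_source` lies in the closed window
#' `[window_s[1], window_s[2]]`; each target event is used at most once. A
#' source-target pairing qualifies for propagation analysis when at least
#' `min_paired_events` pairs exist.
#'
#' @param source_times,target_times Sorted ascending event times (s).
#' @param window_s Closed latency window, default `c(0.001, 0.002)`.
#' @param min_paired_events Qualification threshold (default 30).
#' @param source_electrode,target_electrode Optional ids carried in the result.
#' @return A `paired_events` list: `pairs` (tibble `t_source_s`, `t_target_s`,
#'   `latency_s`), `n_pairs`, `qualified`, and the electrode ids.
#' @export
#' @examples
#' find_paired_events(0.1, 0.1015)$pairs$latency_s  # 1.5 ms
find_paired_events <- function(source_times, target_times,
                               window_s = c(0.001, 0.002),
                               min_paired_events = 30,
                               source_electrode = NA_integer_,
                               target_electrode = NA_integer_) {
  if (is.unsorted(source_times) || is.unsorted(target_times)) {
    abort("event times must be sorted ascending")
  }
  lo <- window_s[1]
  hi <- window_s[2]
  ns <- length(source_times)
  nt <- length(target_times)
  ts <- double(0)
  tt <- double(0)
  j <- 1
  for (i in seq_len(ns)) {
    s <- source_times[i]
    while (j <= nt && target_times[j] < s + lo) j <- j + 1
    if (j > nt) break
    if (target_times[j] <= s + hi) {
      ts <- c(ts, s)
      tt <- c(tt, target_times[j])
      j <- j + 1
    }
  }
  pairs <- tibble(t_source_s = ts, t_target_s = tt, latency_s = tt - ts)
  structure(
    list(pairs = pairs, n_pairs = nrow(pairs),
         qualified = nrow(pairs) >= min_paired_events,
         source_electrode = source_electrode,
         target_electrode = target_electrode,
         window_s = window_s),
    class = "paired_events"
  )
}

#' @export
print.paired_events <- function(x, ...) {
  cat(sprintf("<paired_events> %d pairs (%squalified)\n", x$n_pairs,
              if (x$qualified) "" else "not "))
  invisible(x)
}

#' Fraction of paired windows containing a candidate event
#'
#' For each paired window `[t_source, t_target]` (closed), checks whether the
#' candidate electrode fired at least once inside it.
#'
#' @param pairs A [find_paired_events()] result with at least one pair.
#' @param candidate_times Sorted candidate event times (s).
#' @return Fraction in `[0, 1]`.
#' @export
cooccurrence_fraction <- function(pairs, candidate_times) {
  p <- pairs$pairs
  if (nrow(p) == 0) abort("no paired events")
  if (length(candidate_times) == 0) return(0)
  candidate_times <- sort(candidate_times)
  n_in <- findInterval(p$t_target_s, candidate_times) -
    findInterval(p$t_source_s, candidate_times, left.open = TRUE)
  mean(n_in >= 1)
}

#' Select intermediary electrodes along the principal axis
#'
#' For each anchor fraction (default 25/50/75%), among the band electrodes
#' whose co-occurrence fraction strictly exceeds `min_fraction`, picks the
#' one with axial fraction closest to the anchor; equidistant ties go to the
#' smaller electrode id; anchors with no passing candidate are skipped.
#'
#' @param amap An [axial_map()].
#' @param band_ids Candidate electrode ids from [band_filter()].
#' @param pairs A qualified [find_paired_events()] result.
#' @param spikes A [spike_table()] holding the candidates' events.
#' @param anchors Anchor fractions (default `c(0.25, 0.5, 0.75)`).
#' @param min_fraction Strict co-occurrence threshold (default 0.80).
#' @return Tibble: `anchor`, `electrode_id`, `axial_um`, `axial_fraction`,
#'   `cooccurrence` (zero rows when nothing passes).
#' @export
select_intermediaries <- function(amap, band_ids, pairs, spikes,
                                  anchors = c(0.25, 0.5, 0.75),
                                  min_fraction = 0.80) {
  empty <- tibble(anchor = double(), electrode_id = integer(),
                  axial_um = double(), axial_fraction = double(),
                  cooccurrence = double())
  if (length(band_ids) == 0) return(empty)
  cand <- amap[amap$electrode_id %in% band_ids, ]
  cand$cooccurrence <- vapply(cand$electrode_id, function(id) {
    cooccurrence_fraction(pairs, times_of(spikes, id))
  }, double(1))
  passing <- cand[cand$cooccurrence > min_fraction, ]
  if (nrow(passing) == 0) return(empty)
  rows <- purrr::map(anchors, function(a) {
    d <- abs(passing$axial_fraction - a)
    best <- which(d <= min(d) + 1e-12)
    best <- best[which.min(passing$electrode_id[best])]
    tibble(anchor = a, electrode_id = passing$electrode_id[best],
           axial_um = passing$axial_um[best],
           axial_fraction = passing$axial_fraction[best],
           cooccurrence = passing$cooccurrence[best])
  })
  dplyr::bind_rows(rows)
}

#' Build a latency trace
#'
#' Orders the source, the selected intermediaries, and the target by axial
#' position and attaches each point's median latency relative to the source:
#' 0 at the source; for each intermediary, the median over paired windows of
#' (first candidate event in the window - t_source); the median pair latency
#' at the target.
#'
#' @param pairs A qualified [find_paired_events()] result (with electrode ids).
#' @param intermediaries Result of [select_intermediaries()].
#' @param spikes A [spike_table()].
#' @param amap An [axial_map()] oriented source to target.
#' @return A tibble of class `latency_trace`: `electrode_id`, `axial_um`,
#'   `median_latency_s`, with strictly increasing axial positions.
#' @export
build_latency_trace <- function(pairs, intermediaries, spikes, amap) {
  if (!pairs$qualified) abort("pairs are not qualified for propagation analysis")
  p <- pairs$pairs
  inter <- intermediaries[!duplicated(intermediaries$electrode_id), ,
                          drop = FALSE]
  med_first <- vapply(seq_len(nrow(inter)), function(k) {
    ct <- sort(times_of(spikes, inter$electrode_id[k]))
    first_idx <- findInterval(p$t_source_s, ct, left.open = TRUE) + 1
    ok <- first_idx <= length(ct) & ct[pmin(first_idx, length(ct))] <= p$t_target_s
    if (!any(ok)) return(NA_real_)
    median(ct[first_idx[ok]] - p$t_source_s[ok])
  }, double(1))
  src_ax <- amap$axial_um[amap$electrode_id == pairs$source_electrode]
  tgt_ax <- amap$axial_um[amap$electrode_id == pairs$target_electrode]
  pts <- dplyr::bind_rows(
    tibble(electrode_id = as.integer(pairs$source_electrode),
           axial_um = src_ax, median_latency_s = 0),
    tibble(electrode_id = inter$electrode_id, axial_um = inter$axial_um,
           median_latency_s = med_first),
    tibble(electrode_id = as.integer(pairs$target_electrode),
           axial_um = tgt_ax, median_latency_s = median(p$latency_s))
  )
  pts <- pts[!is.na(pts$median_latency_s), ]
  pts <- pts[order(pts$axial_um), ]
  if (any(diff(pts$axial_um) <= 0)) {
    abort("latency trace axial positions must be strictly increasing")
  }
  class(pts) <- c("latency_trace", class(pts))
  pts
}

#' Fit conduction velocity from a latency trace
#'
#' Ordinary least squares of axial position (mm) against latency (ms); the
#' conduction velocity is the slope in mm/ms. With exactly two points this
#' degenerates to the two-point slope.
#'
#' @param trace A [build_latency_trace()] result (>= 2 points).
#' @return A `velocity_fit`: `velocity_mm_per_ms`, `intercept_mm`,
#'   `sigma_mm`, `r_squared`, `n_points`.
#' @export
#' @examples
#' tr <- tibble::tibble(electrode_id = 1:2, axial_um = c(0, 910),
#'                      median_latency_s = c(0, 0.0014))
#' fit_velocity(tr)$velocity_mm_per_ms  # 0.65
fit_velocity <- function(trace) {
  if (nrow(trace) < 2) abort("velocity fit needs at least 2 points")
  lat_ms <- trace$median_latency_s * 1000
  pos_mm <- trace$axial_um / 1000
  if (diff(range(lat_ms)) == 0) abort("zero latency spread: cannot fit velocity")
  fit <- lm(pos_mm ~ lat_ms)
  # collinear (noiseless) traces are a legitimate input: silence the
  # perfect-fit note from summary.lm
  res <- suppressWarnings(summary(fit))
  structure(
    list(velocity_mm_per_ms = unname(coef(fit)[2]),
         intercept_mm = unname(coef(fit)[1]),
         sigma_mm = res$sigma,
         r_squared = res$r.squared,
         n_points = nrow(trace)),
    class = "velocity_fit"
  )
}

#' @export
print.velocity_fit <- function(x, ...) {
  cat(sprintf("<velocity_fit> %.4f mm/ms (R^2 = %.4f, %d points)\n",
              x$velocity_mm_per_ms, x$r_squared, x$n_points))
  invisible(x)
}

endpoint_electrodes <- function(layout, spec) {
  amap <- axial_map(layout, spec)
  members <- amap[amap$electrode_id %in% spec$member_electrode_ids, ]
  list(
    entry = members$electrode_id[which.min(members$axial_um)],
    exit = members$electrode_id[which.max(members$axial_um)]
  )
}

#' Analyze propagation in one orientation
#'
#' Runs the full pairing pipeline for one source-target orientation of a
#' channel: event pairing in the latency window, orthogonal band filtering,
#' intermediary selection, latency-trace construction, and the velocity fit.
#'
#' @param spikes A [spike_table()] restricted to the channel's electrodes.
#' @param layout The channel's [electrode_layout()].
#' @param spec The [microchannel_spec()].
#' @param cfg An [analysis_config()].
#' @param direction `"forward"` (entry to exit) or `"backward"`.
#' @return List: `pairs`, `intermediaries`, `trace` (`NULL` if unqualified),
#'   `velocity` (`NULL` if no fit), `qualified` (pairs qualified and a
#'   finite positive velocity was fitted).
#' @export
analyze_propagation <- function(spikes, layout, spec,
                                cfg = analysis_config(),
                                direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  cfg <- validate_config(cfg)
  ends <- endpoint_electrodes(layout, spec)
  if (direction == "forward") {
    src_id <- ends$entry; tgt_id <- ends$exit
    amap <- axial_map(layout, spec)
  } else {
    src_id <- ends$exit; tgt_id <- ends$entry
    amap <- axial_map(layout, source_xy_um = spec$exit_xy_um,
                      target_xy_um = spec$entry_xy_um)
  }
  pairs <- find_paired_events(
    times_of(spikes, src_id), times_of(spikes, tgt_id),
    window_s = cfg$latency_window_s,
    min_paired_events = cfg$min_paired_events,
    source_electrode = src_id, target_electrode = tgt_id
  )
  out <- list(pairs = pairs, intermediaries = NULL, trace = NULL,
              velocity = NULL, qualified = FALSE, direction = direction)
  if (!pairs$qualified) return(out)
  band_ids <- band_filter(amap, cfg$band_half_width_um)
  band_ids <- intersect(band_ids, spec$member_electrode_ids)
  inter <- select_intermediaries(amap, band_ids, pairs, spikes,
                                 anchors = cfg$intermediary_anchors,
                                 min_fraction = cfg$cooccurrence_min_fraction)
  out$intermediaries <- inter
  trace <- tryCatch(build_latency_trace(pairs, inter, spikes, amap),
                    error = function(e) NULL)
  if (is.null(trace)) return(out)
  out$trace <- trace
  fit <- tryCatch(fit_velocity(trace), error = function(e) NULL)
  out$velocity <- fit
  out$qualified <- !is.null(fit) && is.finite(fit$velocity_mm_per_ms) &&
    fit$velocity_mm_per_ms > 0
  out
}

#' Classify propagation direction of a channel
#'
#' Runs [analyze_propagation()] in both orientations (source/target at the
#' member electrodes nearest the entry and exit endpoints). An orientation is
#' qualified when its pairing reaches the minimum event count and a finite
#' positive velocity is fitted. Directional channels with entry-to-exit
#' injection classify `forward_only`; straight channels with bidirectional
#' propagation classify `both`; pure background activity classifies `none`.
#'
#' @inheritParams analyze_propagation
#' @return A `direction_report`: `channel_id`, `kind`, `forward_qualified`,
#'   `backward_qualified`, `classification`, and the two orientation analyses
#'   under `forward` / `backward`.
#' @export
classify_direction <- function(spikes, layout, spec, cfg = analysis_config()) {
  fwd <- analyze_propagation(spikes, layout, spec, cfg, "forward")
  bwd <- analyze_propagation(spikes, layout, spec, cfg, "backward")
  classification <- if (fwd$qualified && bwd$qualified) {
    "both"
  } else if (fwd$qualified) {
    "forward_only"
  } else if (bwd$qualified) {
    "backward_only"
  } else {
    "none"
  }
  structure(
    list(channel_id = spec$channel_id, kind = spec$kind,
         forward_qualified = fwd$qualified,
         backward_qualified = bwd$qualified,
         classification = classification,
         forward = fwd, backward = bwd),
    class = "direction_report"
  )
}

#' @export
print.direction_report <- function(x, ...) {
  cat(sprintf("<direction_report> %s (%s): %s\n", x$channel_id, x$kind,
              x$classification))
  invisible(x)
}
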