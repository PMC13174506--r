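#' Analysis configuration
#'
#' Bundles every tunable threshold of the propagation and flux pipeline with
#' the field-standard defaults: spike detection at 3.5 times the trace RMS,
#' removal of inter-spike intervals below 1 ms, a closed 1--2 ms source-target
#' latency window, a minimum of 30 paired events for a channel to qualify, a
#' 17.5 um orthogonal search band (one electrode pitch), intermediary anchors
#' at 25/50/75% of the principal axis with a strict >80% co-occurrence rule,
#' quartile-based flux ratios, and 5% profile bins.
#'
#' @param rms_threshold_multiple Detection threshold as a multiple of the
#'   per-electrode RMS (dimensionless, default 3.5).
#' @param isi_min_s Minimum inter-spike interval in seconds; closer events are
#'   treated as duplicates and removed (default 0.001).
#' @param latency_window_s Closed latency window `c(lower, upper)` in seconds
#'   for source-target pairing (default `c(0.001, 0.002)`).
#' @param min_paired_events Minimum number of paired events for a
#'   source-target orientation to qualify (default 30).
#' @param band_half_width_um Half-width of the orthogonal search band around
#'   the principal axis, inclusive (default 17.5 um, one electrode pitch).
#' @param intermediary_anchors Axial fractions at which intermediary
#'   electrodes are anchored (default `c(0.25, 0.5, 0.75)`).
#' @param cooccurrence_min_fraction Minimum fraction of paired windows in
#'   which an intermediary candidate must fire; the comparison is strict
#'   (default 0.80).
#' @param profile_bin_fraction Axial bin width, as a fraction of channel
#'   length, for firing-rate profiles (default 0.05; must divide 1 evenly).
#' @param alpha Significance level for the per-channel asymmetry test
#'   (default 0.05).
#' @param rms_method `"rms"` for the plain root-mean-square of the whole
#'   trace (default) or `"mad"` for the robust median-absolute-deviation
#'   estimate (MAD / 0.6745).
#' @param p_adjust_method Multiple-testing correction applied across channels
#'   in [condition_summary()]; `"none"` (default, per-channel alpha) or any
#'   method accepted by [stats::p.adjust()].
#' @param random_seed Optional integer seed recorded with the configuration.
#'
#' @return A validated `analysis_config` list with all fields explicit
#'   (`n_quartiles` is fixed at 4).
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$rms_threshold_multiple
analysis_config <- function(rms_threshold_multiple = 3.5,
                            isi_min_s = 0.001,
                            latency_window_s = c(0.001, 0.002),
                            min_paired_events = 30,
                            band_half_width_um = 17.5,
                            intermediary_anchors = c(0.25, 0.5, 0.75),
                            cooccurrence_min_fraction = 0.80,
                            profile_bin_fraction = 0.05,
                            alpha = 0.05,
                            rms_method = c("rms", "mad"),
                            p_adjust_method = "none",
                            random_seed = NULL) {
  cfg <- list(
    rms_threshold_multiple = rms_threshold_multiple,
    isi_min_s = isi_min_s,
    latency_window_s = latency_window_s,
    min_paired_events = min_paired_events,
    band_half_width_um = band_half_width_um,
    intermediary_anchors = intermediary_anchors,
    cooccurrence_min_fraction = cooccurrence_min_fraction,
    n_quartiles = 4L,
    profile_bin_fraction = profile_bin_fraction,
    alpha = alpha,
    rms_method = match.arg(rms_method),
    p_adjust_method = p_adjust_method,
    random_seed = random_seed
  )
  validate_config(cfg)
}

#' Validate and normalize an analysis configuration
#'
#' Fills unspecified fields with defaults and enforces every invariant,
#' reporting the offending field by name. Accepts a partial named list (for
#' example parsed from YAML/JSON) or an existing `analysis_config`.
#'
#' @param cfg Named list of configuration fields; missing fields take the
#'   defaults of [analysis_config()].
#' @return A fully explicit `analysis_config`.
#' @export
#' @examples
#' validate_config(list(alpha = 0.01))$alpha
validate_config <- function(cfg = list()) {
  if (inherits(cfg, "analysis_config")) cfg <- unclass(cfg)
  if (!is.list(cfg)) abort("`cfg` must be a named list of configuration fields")
  defaults <- list(
    rms_threshold_multiple = 3.5, isi_min_s = 0.001,
    latency_window_s = c(0.001, 0.002), min_paired_events = 30,
    band_half_width_um = 17.5, intermediary_anchors = c(0.25, 0.5, 0.75),
    cooccurrence_min_fraction = 0.80, n_quartiles = 4L,
    profile_bin_fraction = 0.05, alpha = 0.05, rms_method = "rms",
    p_adjust_method = "none", random_seed = NULL
  )
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  out <- utils::modifyList(defaults, cfg[!vapply(cfg, is.null, logical(1))])

  check_pos <- function(field) {
    v <- out[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(paste0("config field `", field, "` must be a positive number"))
    }
  }
  for (f in c("rms_threshold_multiple", "isi_min_s", "min_paired_events",
              "alpha", "profile_bin_fraction")) {
    check_pos(f)
  }
  if (!is.numeric(out$band_half_width_um) || out$band_half_width_um < 0) {
    abort("config field `band_half_width_um` must be >= 0")
  }
  w <- out$latency_window_s
  if (!is.numeric(w) || length(w) != 2 || any(!is.finite(w)) || any(w <= 0)) {
    abort("config field `latency_window_s` must be two positive numbers")
  }
  if (w[1] >= w[2]) {
    abort("config field `latency_window_s`: lower bound must be < upper bound")
  }
  cf <- out$cooccurrence_min_fraction
  if (!is.numeric(cf) || length(cf) != 1 || cf <= 0 || cf >= 1) {
    abort("config field `cooccurrence_min_fraction` must lie in (0, 1)")
  }
  an <- out$intermediary_anchors
  if (!is.numeric(an) || any(an <= 0) || any(an >= 1)) {
    abort("config field `intermediary_anchors` must lie strictly in (0, 1)")
  }
  if (out$n_quartiles != 4L) abort("config field `n_quartiles` is fixed at 4")
  nb <- 1 / out$profile_bin_fraction
  if (abs(nb - round(nb)) > 1e-9) {
    abort("config field `profile_bin_fraction` must divide 1 evenly")
  }
  if (!out$rms_method %in% c("rms", "mad")) {
    abort("config field `rms_method` must be \"rms\" or \"mad\"")
  }
  if (!is.null(out$random_seed)) {
    out$random_seed <- as.integer(out$random_seed)
  }
  out$min_paired_events <- as.integer(out$min_paired_events)
  structure(out, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (f in setdiff(names(x), "random_seed")) {
    cat(sprintf("  %-26s %s\n", f, paste(format(x[[f]]), collapse = ", ")))
  }
  if (!is.null(x$random_seed)) cat("  random_seed               ", x$random_seed, "\n")
  invisible(x)
}
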