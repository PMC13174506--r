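#' Per-track neurite extension velocity
#'
#' Velocity is net displacement over elapsed time — (final - initial axial
#' position) / elapsed hours — which matches mean displacement as a function
#' of time and is robust to missed frames.
#'
#' @param tracks Tibble with `track_id`, `condition`, `hour`,
#'   `axial_position_um` (at least two observations per track, hours
#'   strictly increasing).
#' @return Tibble: `track_id`, `condition`, `velocity_um_per_hr`,
#'   `n_observations`.
#' @export
#' @examples
#' tr <- tibble::tibble(track_id = "a", condition = "permissive",
#'                      hour = 0:16, axial_position_um = 10 * (0:16))
#' track_velocity(tr)$velocity_um_per_hr  # 10
track_velocity <- function(tracks) {
  if (any(tracks$axial_position_um < 0)) abort("positions must be >= 0")
  out <- tracks |>
    dplyr::group_by(track_id = .data$track_id,
                    condition = .data$condition) |>
    dplyr::arrange(.data$hour, .by_group = TRUE) |>
    dplyr::summarise(
      n_observations = dplyr::n(),
      elapsed_hr = max(.data$hour) - min(.data$hour),
      velocity_um_per_hr =
        (dplyr::last(.data$axial_position_um) -
           dplyr::first(.data$axial_position_um)) / .data$elapsed_hr,
      .groups = "drop"
    )
  if (any(out$n_observations < 2)) {
    abort("every track needs at least 2 observations")
  }
  dplyr::select(out, "track_id", "condition", "velocity_um_per_hr",
                "n_observations")
}

#' Outgrowth regression on median track positions
#'
#' Computes the median axial position across tracks at each hour, then fits
#' ordinary least squares of median position against hour. The slope is the
#' cohort outgrowth rate in um/hr.
#'
#' @param tracks Track tibble for one condition (`hour`,
#'   `axial_position_um`; >= 2 distinct hours).
#' @return An `outgrowth_fit`: `slope_um_per_hr`, `intercept_um`,
#'   `r_squared`, `n_hours`, and the per-hour medians under `medians`.
#' @export
outgrowth_regression <- function(tracks) {
  med <- tracks |>
    dplyr::group_by(hour = .data$hour) |>
    dplyr::summarise(median_um = median(.data$axial_position_um),
                     .groups = "drop")
  if (nrow(med) < 2) abort("need at least 2 time points")
  fit <- lm(median_um ~ hour, data = med)
  res <- suppressWarnings(summary(fit))  # deterministic cohorts fit exactly
  structure(
    list(slope_um_per_hr = unname(coef(fit)[2]),
         intercept_um = unname(coef(fit)[1]),
         r_squared = res$r.squared, n_hours = nrow(med), medians = med),
    class = "outgrowth_fit"
  )
}

#' @export
print.outgrowth_fit <- function(x, ...) {
  cat(sprintf("<outgrowth_fit> %.2f um/hr (R^2 = %.3f over %d time points)\n",
              x$slope_um_per_hr, x$r_squared, x$n_hours))
  invisible(x)
}

#' Traversal extent from an axial intensity profile
#'
#' Thresholds the fluorescence profile at background mean + 3 background sd
#' (the conventional detection criterion). The background window is the
#' distal tail (default the last 5%) of a reference profile — by default the
#' profile itself, but a neurite-free reference such as the prohibitive-side
#' profile can be supplied when signal spans the whole channel. The extent
#' is the farthest axial position with supra-threshold intensity, as a
#' percentage of channel length (0 if none).
#'
#' @param profile Tibble with `axial_um` (ascending) and `intensity`.
#' @param channel_length_um Channel length in um.
#' @param background_window_fraction Fraction of the channel, at the distal
#'   end, used as background (default 0.05; must contain >= 5 samples).
#' @param sd_multiple Threshold multiple of the background sd (default 3).
#' @param reference Optional profile supplying the background window
#'   (default: `profile`).
#' @return Extent as percent of channel length (0 to 100).
#' @export
traversal_extent <- function(profile, channel_length_um,
                             background_window_fraction = 0.05,
                             sd_multiple = 3, reference = NULL) {
  if (any(profile$intensity < 0)) abort("intensities must be >= 0")
  if (is.unsorted(profile$axial_um)) abort("profile positions must ascend")
  reference <- reference %||% profile
  bg <- reference$intensity[
    reference$axial_um >= channel_length_um * (1 - background_window_fraction)]
  if (length(bg) < 5) abort("background window must contain at least 5 samples")
  threshold <- mean(bg) + sd_multiple * sd(bg)
  over <- profile$axial_um[profile$intensity > threshold]
  if (length(over) == 0) return(0)
  100 * max(over) / channel_length_um
}

#' Full-crossing success rate
#'
#' Percentage of channels whose traversal extent reaches the full-crossing
#' threshold (default 95% of channel length, allowing for pixelation of the
#' fluorescence profile at the exit).
#'
#' @param extents Traversal extents in percent (non-empty).
#' @param full_crossing_threshold_pct Threshold in percent (default 95).
#' @return Percentage of successful channels.
#' @export
#' @examples
#' success_rate(c(rep(100, 19), rep(40, 8)))  # 70.4 (19 of 27)
success_rate <- function(extents, full_crossing_threshold_pct = 95) {
  if (length(extents) == 0) abort("no extents given")
  100 * sum(extents >= full_crossing_threshold_pct) / length(extents)
}

#' Group comparisons of outgrowth measurements
#'
#' Pairwise two-sided Welch t tests between all condition pairs, and — when
#' a control condition is named — Dunnett many-to-one adjusted comparisons
#' against it (single-step adjustment on an ANOVA fit).
#'
#' @param data Tibble with a `condition` column and a `value` column
#'   (velocities or extents; >= 2 observations per group).
#' @param value Name of the value column (default `"value"`).
#' @param control_label Optional control condition for the Dunnett branch.
#' @return A `group_comparison` list: `pairwise` tibble (`group_a`,
#'   `group_b`, `t_statistic`, `p_value`) and `dunnett` tibble
#'   (`group`, `estimate`, `p_unadjusted`, `p_adjusted`) or `NULL`.
#' @export
group_comparison <- function(data, value = "value", control_label = NULL) {
  data <- tibble(condition = as.character(data$condition),
                 value = data[[value]])
  groups <- split(data$value, data$condition)
  if (length(groups) < 2) abort("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2)) {
    abort("every group needs at least 2 observations")
  }
  combos <- utils::combn(names(groups), 2)
  pairwise <- purrr::map(seq_len(ncol(combos)), function(k) {
    a <- combos[1, k]
    b <- combos[2, k]
    tt <- t.test(groups[[a]], groups[[b]])
    tibble(group_a = a, group_b = b,
           t_statistic = unname(tt$statistic),
           p_value = tt$p.value)
  }) |> dplyr::bind_rows()
  dunnett <- NULL
  if (!is.null(control_label)) {
    if (!control_label %in% names(groups)) {
      abort("`control_label` is not one of the conditions")
    }
    df <- data
    df$condition <- stats::relevel(factor(df$condition), ref = control_label)
    fit <- aov(value ~ condition, data = df)
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(condition = "Dunnett"))
    sm <- summary(gl)
    sm_raw <- summary(gl, test = multcomp::adjusted("none"))
    labels <- sub(paste0(" - ", control_label, "$"), "",
                  names(sm$test$coefficients))
    dunnett <- tibble(group = labels,
                      estimate = unname(sm$test$coefficients),
                      p_unadjusted = unname(as.vector(sm_raw$test$pvalues)),
                      p_adjusted = unname(as.vector(sm$test$pvalues)))
  }
  structure(list(pairwise = pairwise, dunnett = dunnett,
                 control_label = control_label),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  print(x$pairwise)
  if (!is.null(x$dunnett)) {
    cat(sprintf("Dunnett vs %s:\n", x$control_label))
    print(x$dunnett)
  }
  invisible(x)
}

#' Write and read neurite track and profile tables
#'
#' Track table CSV: `track_id,condition,hour,axial_position_um`. Profile
#' CSV: `channel_id,axial_um,intensity` (one row per sampled position).
#'
#' @param tracks,profiles Tibbles as produced by
#'   [simulate_neurite_dataset()].
#' @param path CSV path.
#' @return `path` invisibly; readers return tibbles.
#' @export
write_track_csv <- function(tracks, path) {
  utils::write.csv(tracks[, c("track_id", "condition", "hour",
                              "axial_position_um")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname write_track_csv
#' @export
write_profile_csv <- function(profiles, path) {
  utils::write.csv(profiles[, c("channel_id", "axial_um", "intensity")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_profile_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
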