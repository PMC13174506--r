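#' Tidy a velocity fit
#'
#' @param x A `velocity_fit` from [fit_velocity()].
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @export
tidy.velocity_fit <- function(x, ...) {
  tibble(term = c("intercept_mm", "velocity_mm_per_ms"),
         estimate = c(x$intercept_mm, x$velocity_mm_per_ms))
}

#' @rdname tidy.velocity_fit
#' @export
glance.velocity_fit <- function(x, ...) {
  tibble(velocity_mm_per_ms = x$velocity_mm_per_ms,
         r_squared = x$r_squared, sigma_mm = x$sigma_mm,
         n_points = x$n_points)
}

#' Tidy an outgrowth regression
#'
#' @param x An `outgrowth_fit` from [outgrowth_regression()].
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @export
tidy.outgrowth_fit <- function(x, ...) {
  tibble(term = c("intercept_um", "slope_um_per_hr"),
         estimate = c(x$intercept_um, x$slope_um_per_hr))
}

#' @rdname tidy.outgrowth_fit
#' @export
glance.outgrowth_fit <- function(x, ...) {
  tibble(slope_um_per_hr = x$slope_um_per_hr, r_squared = x$r_squared,
         n_hours = x$n_hours)
}

#' Tidy a direction report
#'
#' @param x A `direction_report` from [classify_direction()].
#' @param ... Unused.
#' @return One-row tibble with the qualification flags, classification, pair
#'   counts and fitted velocities per orientation.
#' @export
tidy.direction_report <- function(x, ...) {
  vel <- function(side) {
    if (is.null(side$velocity)) NA_real_ else side$velocity$velocity_mm_per_ms
  }
  tibble(channel_id = x$channel_id, kind = x$kind,
         forward_qualified = x$forward_qualified,
         backward_qualified = x$backward_qualified,
         classification = x$classification,
         forward_pairs = x$forward$pairs$n_pairs,
         backward_pairs = x$backward$pairs$n_pairs,
         forward_velocity_mm_per_ms = vel(x$forward),
         backward_velocity_mm_per_ms = vel(x$backward))
}

#' Tidy a condition summary
#'
#' @param x A `condition_summary` from [condition_summary()].
#' @param ... Unused.
#' @return The per-condition summary tibble.
#' @export
tidy.condition_summary <- function(x, ...) x$by_condition

#' Tidy a group comparison
#'
#' @param x A `group_comparison` from [group_comparison()].
#' @param ... Unused.
#' @return The pairwise Welch tibble, with Dunnett-adjusted p-values joined
#'   when available.
#' @export
tidy.group_comparison <- function(x, ...) x$pairwise
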