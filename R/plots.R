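#' Plot a latency trace
#'
#' Axial position against median latency, with the least-squares conduction
#' line whose slope (mm/ms) is the velocity estimate.
#'
#' @param object A `latency_trace` from [build_latency_trace()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.latency_trace <- function(object, ...) {
  df <- as_tibble(object)
  df$latency_ms <- df$median_latency_s * 1000
  ggplot2::ggplot(df, ggplot2::aes(x = .data$latency_ms,
                                   y = .data$axial_um / 1000)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey50", linewidth = 0.5) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "median latency (ms)", y = "axial position (mm)",
                  title = "Propagation latency trace")
}

#' Plot a binned firing-rate profile
#'
#' Normalized firing rate (relative to the entry quartile) along the
#' channel; empty bins are omitted.
#'
#' @param object A `flux_profile` from [binned_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flux_profile <- function(object, ...) {
  df <- as_tibble(object[!object$empty, ])
  df$mid <- (df$bin_lo + df$bin_hi) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$normalized_rate)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_col(width = 0.8 * (df$bin_hi[1] - df$bin_lo[1])) +
    ggplot2::labs(x = "axial fraction", y = "firing rate / Q1 mean",
                  title = "Firing-rate profile along channel")
}

#' Plot neurite outgrowth medians with the fitted line
#'
#' Median track position per hour with interquartile ribbon and the
#' ordinary-least-squares outgrowth line, by condition.
#'
#' @param tracks Track tibble (`condition`, `hour`, `axial_position_um`).
#' @return A ggplot object.
#' @export
plot_outgrowth <- function(tracks) {
  med <- tracks |>
    dplyr::group_by(condition = .data$condition, hour = .data$hour) |>
    dplyr::summarise(median_um = median(.data$axial_position_um),
                     q1 = stats::quantile(.data$axial_position_um, 0.25),
                     q3 = stats::quantile(.data$axial_position_um, 0.75),
                     .groups = "drop")
  ggplot2::ggplot(med, ggplot2::aes(x = .data$hour, y = .data$median_um,
                                    colour = .data$condition,
                                    fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dashed", linewidth = 0.5) +
    ggplot2::labs(x = "hour", y = "median axial position (um)",
                  title = "Neurite outgrowth")
}
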