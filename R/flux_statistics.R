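#' Per-quartile firing rates along a channel
#'
#' Each electrode's rate is its event count over the recording duration; a
#' quartile's value is the unweighted mean over its electrodes. Quartiles are
#' half-open bins of axial fraction (`[0, 0.25)` is Q1; fraction 1 falls in
#' Q4), so they are robust to irregular electrode subsets.
#'
#' @param spikes A [spike_table()].
#' @param amap An [axial_map()] listing the channel's electrodes (the
#'   electrode universe: silent electrodes count with rate 0).
#' @param duration_s Recording duration (defaults to the spike table's).
#' @return List with `per_electrode` (tibble: `electrode_id`,
#'   `axial_fraction`, `quartile`, `n_events`, `rate_hz`) and
#'   `quartile_means` (tibble: `quartile`, `n_electrodes`, `mean_rate_hz`).
#' @export
quartile_rates <- function(spikes, amap, duration_s = spike_duration(spikes)) {
  if (duration_s <= 0) abort("duration must be > 0")
  frac <- pmin(pmax(amap$axial_fraction, 0), 1)
  counts <- table(factor(spikes$electrode_id[
    spikes$electrode_id %in% amap$electrode_id],
    levels = amap$electrode_id))
  per <- tibble(
    electrode_id = amap$electrode_id,
    axial_fraction = amap$axial_fraction,
    quartile = bin_index(frac, 4L) + 1L,
    n_events = as.integer(counts),
    rate_hz = as.integer(counts) / duration_s
  )
  qm <- per |>
    dplyr::group_by(quartile = .data$quartile) |>
    dplyr::summarise(n_electrodes = dplyr::n(),
                     mean_rate_hz = mean(.data$rate_hz), .groups = "drop")
  qm <- dplyr::left_join(tibble(quartile = 1:4), qm, by = "quartile")
  list(per_electrode = per, quartile_means = qm)
}

#' Flux ratio
#'
#' Ratio of the exit-quartile (Q4) to entry-quartile (Q1) mean firing rate.
#' When the entry quartile is essentially silent (Q1 < 1e-6 Hz) the ratio is
#' undefined and returned as `NA` so it can be excluded from cross-channel
#' statistics rather than clamped.
#'
#' @param q1_rate,q4_rate Quartile mean rates in Hz (>= 0).
#' @return The ratio `q4_rate / q1_rate`, or `NA` when undefined.
#' @export
#' @examples
#' flux_ratio(2.6, 7.7)  # ~ 2.96, the roughly threefold asymmetry
flux_ratio <- function(q1_rate, q4_rate) {
  if (q1_rate < 0 || q4_rate < 0) abort("rates must be >= 0")
  if (q1_rate < 1e-6) return(NA_real_)
  q4_rate / q1_rate
}

#' Binned firing-rate profile along a channel
#'
#' Mean electrode firing rate in axial bins (default 5% of channel length),
#' normalized by the entry-quartile mean (electrodes at fraction
#' `[0, 0.25)`), to illustrate how rates change along a microchannel. Empty
#' bins are flagged, not zero-filled.
#'
#' @inheritParams quartile_rates
#' @param bin_fraction Bin width as a fraction of channel length; must
#'   divide 1 evenly (default 0.05).
#' @return A tibble of class `flux_profile`: `bin`, `bin_lo`, `bin_hi`,
#'   `n_electrodes`, `mean_rate_hz`, `normalized_rate`, `empty`.
#' @export
binned_profile <- function(spikes, amap, duration_s = spike_duration(spikes),
                           bin_fraction = 0.05) {
  n_bins <- 1 / bin_fraction
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    abort("bin_fraction must divide 1 evenly")
  }
  n_bins <- as.integer(round(n_bins))
  qr <- quartile_rates(spikes, amap, duration_s)
  per <- qr$per_electrode
  per$bin <- bin_index(pmin(pmax(per$axial_fraction, 0), 1), n_bins)
  denom <- mean(per$rate_hz[per$quartile == 1L])
  by_bin <- per |>
    dplyr::group_by(bin = .data$bin) |>
    dplyr::summarise(n_electrodes = dplyr::n(),
                     mean_rate_hz = mean(.data$rate_hz), .groups = "drop")
  out <- dplyr::left_join(
    tibble(bin = 0:(n_bins - 1L)), by_bin, by = "bin") |>
    dplyr::mutate(
      bin_lo = .data$bin / n_bins, bin_hi = (.data$bin + 1L) / n_bins,
      n_electrodes = dplyr::coalesce(.data$n_electrodes, 0L),
      empty = .data$n_electrodes == 0L,
      normalized_rate = .data$mean_rate_hz / denom
    ) |>
    dplyr::select("bin", "bin_lo", "bin_hi", "n_electrodes", "mean_rate_hz",
                  "normalized_rate", "empty")
  attr(out, "q1_mean_rate_hz") <- denom
  class(out) <- c("flux_profile", class(out))
  out
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison. The U statistic is computed from ranks
#' (ties contribute 1/2). The p-value is exact by enumeration when both
#' samples have at most 12 observations and no ties occur, and otherwise
#' uses the normal approximation with tie and continuity correction.
#'
#' @param sample_a,sample_b Non-empty numeric samples.
#' @return List: `U` (for `sample_a`), `p_value`, `method` (`"exact"` or
#'   `"normal_approximation"`).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(10, 11, 12))  # U = 0, exact p = 0.1
mann_whitney_u <- function(sample_a, sample_b) {
  na <- length(sample_a)
  nb <- length(sample_b)
  if (na == 0 || nb == 0) abort("both samples must be non-empty")
  r <- rank(c(sample_a, sample_b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  use_exact <- na <= 12 && nb <= 12 && !ties
  wt <- suppressWarnings(
    wilcox.test(sample_a, sample_b, alternative = "two.sided",
                exact = use_exact, correct = TRUE)
  )
  list(U = unname(u), p_value = unname(wt$p.value),
       method = if (use_exact) "exact" else "normal_approximation")
}

#' Per-channel firing-rate asymmetry report
#'
#' Compares the per-electrode firing rates of the entry (Q1) and exit (Q4)
#' quartiles with a two-sided Mann-Whitney U test (no multiple-testing
#' correction, per-channel alpha), and attaches the flux ratio.
#'
#' @inheritParams quartile_rates
#' @param alpha Significance level (default 0.05).
#' @param channel_id,kind Identifiers carried into the report.
#' @return A one-row tibble of class `flux_report`: quartile mean rates
#'   `q1_rate_hz` .. `q4_rate_hz`, `flux_ratio`, `flux_undefined`,
#'   `u_statistic`, `p_value`, `significant`, `n_q1`, `n_q4`, plus
#'   list-columns `q1_rates` and `q4_rates` with the electrode-level rates.
#' @export
channel_asymmetry <- function(spikes, amap,
                              duration_s = spike_duration(spikes),
                              alpha = 0.05, channel_id = "ch1",
                              kind = NA_character_) {
  qr <- quartile_rates(spikes, amap, duration_s)
  per <- qr$per_electrode
  q1 <- per$rate_hz[per$quartile == 1L]
  q4 <- per$rate_hz[per$quartile == 4L]
  if (length(q1) == 0 || length(q4) == 0) {
    abort("both Q1 and Q4 need at least one electrode")
  }
  mw <- mann_whitney_u(q1, q4)
  qm <- qr$quartile_means$mean_rate_hz
  fr <- flux_ratio(qm[1], qm[4])
  out <- tibble(
    channel_id = channel_id, kind = kind,
    q1_rate_hz = qm[1], q2_rate_hz = qm[2], q3_rate_hz = qm[3],
    q4_rate_hz = qm[4],
    flux_ratio = fr, flux_undefined = is.na(fr),
    u_statistic = mw$U, p_value = mw$p_value,
    significant = mw$p_value < alpha,
    n_q1 = length(q1), n_q4 = length(q4),
    q1_rates = list(q1), q4_rates = list(q4)
  )
  class(out) <- c("flux_report", class(out))
  out
}

#' Summarise flux reports across conditions
#'
#' Per condition: channel counts, undefined-ratio exclusions, mean and median
#' flux ratio, and the percentage of channels with a significant Q1-vs-Q4
#' asymmetry. With exactly two conditions, the defined flux ratios are also
#' compared across conditions with a Mann-Whitney U test.
#'
#' @param reports A `flux_report` tibble (rows from [channel_asymmetry()],
#'   stacked with [dplyr::bind_rows()]), with condition labels in `kind`.
#' @param alpha Significance level used to recount significant channels.
#' @param p_adjust_method Optional correction across channels (any
#'   [stats::p.adjust()] method; `"none"` replicates the per-channel
#'   procedure and is the default).
#' @return A `condition_summary` list: `by_condition` tibble
#'   (`kind`, `n_channels`, `n_undefined`, `mean_flux_ratio`,
#'   `median_flux_ratio`, `percent_significant`), and `cross_comparison`
#'   (`U`, `p_value`) when two conditions are present.
#' @export
condition_summary <- function(reports, alpha = 0.05,
                              p_adjust_method = "none") {
  if (nrow(reports) == 0) abort("no flux reports given")
  reports$p_adj <- stats::p.adjust(reports$p_value, method = p_adjust_method)
  by_condition <- reports |>
    dplyr::group_by(kind = .data$kind) |>
    dplyr::summarise(
      n_channels = dplyr::n(),
      n_undefined = sum(.data$flux_undefined),
      mean_flux_ratio = mean(.data$flux_ratio[!.data$flux_undefined]),
      median_flux_ratio = median(.data$flux_ratio[!.data$flux_undefined]),
      percent_significant = 100 * mean(.data$p_adj < alpha),
      .groups = "drop"
    )
  if (all(reports$flux_undefined)) abort("all flux ratios are undefined")
  cross <- NULL
  kinds <- unique(reports$kind)
  if (length(kinds) == 2) {
    a <- reports$flux_ratio[reports$kind == kinds[1] & !reports$flux_undefined]
    b <- reports$flux_ratio[reports$kind == kinds[2] & !reports$flux_undefined]
    if (length(a) > 0 && length(b) > 0) {
      mw <- mann_whitney_u(a, b)
      cross <- tibble(kind_a = kinds[1], kind_b = kinds[2], U = mw$U,
                      p_value = mw$p_value)
    }
  }
  structure(list(by_condition = by_condition, cross_comparison = cross,
                 alpha = alpha, p_adjust_method = p_adjust_method),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat("<condition_summary>\n")
  print(x$by_condition)
  if (!is.null(x$cross_comparison)) {
    cat(sprintf("cross-condition Mann-Whitney p = %.3g\n",
                x$cross_comparison$p_value))
  }
  invisible(x)
}

#' Write a per-channel flux results table
#'
#' One TSV row per channel: ids, quartile rates, flux ratio, U, p,
#' significance (list columns are dropped).
#'
#' @param reports A `flux_report` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(reports, path) {
  flat <- reports[, !vapply(reports, is.list, logical(1)), drop = FALSE]
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
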