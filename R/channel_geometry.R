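#' Map electrodes onto a channel's principal axis
#'
#' Orthogonally decomposes each electrode position relative to the straight
#' principal axis between the channel entry (source side) and exit (target
#' side): a signed axial projection, its fraction of the axis length, and an
#' unsigned orthogonal offset. Fractions outside `[0, 1]` are kept and
#' flagged (`beyond_endpoints`) for electrodes past the endpoints.
#'
#' @param layout An [electrode_layout()] (a data frame with `electrode_id`,
#'   `x_um`, `y_um`).
#' @param spec A [microchannel_spec()], or `NULL` if `source_xy_um` /
#'   `target_xy_um` are given directly.
#' @param source_xy_um,target_xy_um Optional explicit axis endpoints (um).
#' @return A tibble of class `axial_map`: `electrode_id`, `axial_um`,
#'   `axial_fraction`, `orthogonal_offset_um`, `beyond_endpoints`; axis
#'   length kept as attribute `axis_length_um`.
#' @export
#' @examples
#' ch <- build_channel_layout(910, 17.5, "straight")
#' axial_map(ch$layout, ch$spec)
axial_map <- function(layout, spec = NULL, source_xy_um = NULL,
                      target_xy_um = NULL) {
  if (!is.null(spec)) {
    source_xy_um <- spec$entry_xy_um
    target_xy_um <- spec$exit_xy_um
  }
  if (is.null(source_xy_um) || is.null(target_xy_um)) {
    abort("give either `spec` or both `source_xy_um` and `target_xy_um`")
  }
  axis <- target_xy_um - source_xy_um
  len <- sqrt(sum(axis^2))
  if (len == 0) abort("axis endpoints coincide")
  u <- axis / len
  dx <- layout$x_um - source_xy_um[1]
  dy <- layout$y_um - source_xy_um[2]
  axial <- dx * u[1] + dy * u[2]
  ortho <- abs(dx * u[2] - dy * u[1])
  out <- tibble(
    electrode_id = layout$electrode_id,
    axial_um = axial,
    axial_fraction = axial / len,
    orthogonal_offset_um = ortho,
    beyond_endpoints = axial < -1e-9 | axial > len + 1e-9
  )
  attr(out, "axis_length_um") <- len
  class(out) <- c("axial_map", class(out))
  out
}

#' Orthogonal search-band filter
#'
#' Retains electrodes whose orthogonal offset from the principal axis is at
#' most `half_width_um` (inclusive, so the adjacent electrode row at exactly
#' one pitch is captured) and that lie strictly between the endpoints
#' (`0 < axial_fraction < 1`) — the candidate pool for intermediaries.
#'
#' @param amap An [axial_map()].
#' @param half_width_um Band half-width in um (>= 0).
#' @return Integer vector of electrode ids.
#' @export
band_filter <- function(amap, half_width_um = 17.5) {
  if (half_width_um < 0) abort("half_width_um must be >= 0")
  keep <- amap$orthogonal_offset_um <= half_width_um &
    amap$axial_fraction > 1e-12 & amap$axial_fraction < 1 - 1e-12
  amap$electrode_id[keep]
}

#' Axial bin index
#'
#' Half-open bins `[i/n, (i+1)/n)` over the axial fraction; fraction 1.0
#' falls in the last bin. `n_bins = 4` gives the entry/exit quartiles.
#'
#' @param axial_fraction Fractions in `[0, 1]`.
#' @param n_bins Number of bins (>= 1).
#' @return Integer bin indices in `0:(n_bins - 1)`.
#' @export
#' @examples
#' bin_index(c(0, 0.25, 1), 4)  # 0 1 3
bin_index <- function(axial_fraction, n_bins) {
  if (any(axial_fraction < 0 | axial_fraction > 1)) {
    abort("axial_fraction must lie in [0, 1]")
  }
  pmin(as.integer(floor(axial_fraction * n_bins)), n_bins - 1L)
}
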