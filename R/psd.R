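#' Binned volumetric particle size distribution
#'
#' Laser-diffraction style distribution: per-bin volume percentages over
#' strictly increasing size-bin edges. Bin membership elsewhere in the
#' package is decided by the geometric bin centre `sqrt(low * high)`
#' (sizing instruments report log-spaced bins); boundary bins are never
#' split.
#'
#' @param bin_low_um,bin_high_um Bin edges (micrometres), `low < high` per
#'   bin and non-overlapping increasing bins.
#' @param volume_percent Volume share per bin (percent); must sum to 100
#'   (tolerance 1e-6) unless `normalize = TRUE`.
#' @param label Sample label.
#' @param normalize Rescale volumes to sum to exactly 100.
#' @return Object of class `particle_size_distribution` (a data frame with
#'   an extra `center_um` column).
#' @export
particle_size_distribution <- function(bin_low_um, bin_high_um,
                                       volume_percent, label = "",
                                       normalize = FALSE) {
  n <- length(volume_percent)
  if (length(bin_low_um) != n || length(bin_high_um) != n)
    stop_pk("bin edge and volume lengths differ", class = "invalid_psd")
  if (any(bin_high_um <= bin_low_um))
    stop_pk("each bin needs high > low", class = "invalid_psd")
  if (is.unsorted(bin_low_um, strictly = TRUE) ||
      any(bin_low_um[-1L] < bin_high_um[-n] - 1e-9))
    stop_pk("bins must be increasing and non-overlapping",
            class = "invalid_psd")
  if (any(volume_percent < 0))
    stop_pk("volumes must be >= 0", class = "invalid_psd")
  total <- sum(volume_percent)
  if (normalize) {
    if (total <= 0) stop_pk("cannot normalize zero volume",
                            class = "invalid_psd")
    volume_percent <- volume_percent / total * 100
  } else if (abs(total - 100) > 1e-6) {
    stop_pk("volumes sum to ", total, ", not 100 (set normalize = TRUE ",
            "to rescale)", class = "invalid_psd")
  }
  center <- ifelse(bin_low_um > 0, sqrt(bin_low_um * bin_high_um),
                   (bin_low_um + bin_high_um) / 2)
  structure(data.frame(bin_low_um = bin_low_um, bin_high_um = bin_high_um,
                       center_um = center, volume_percent = volume_percent),
            label = label,
            class = c("particle_size_distribution", "data.frame"))
}

#' Cotyledon-cell yield from a particle size distribution
#'
#' Volumetric fraction of particles in the individual-cotyledon-cell size
#' window, obtained by summing the volume of all bins whose geometric
#' centre lies in `[lo, hi]`. The default window 76-133 um is the
#' wet-sieving size class of intact pulse cotyledon cells.
#'
#' @param p A [particle_size_distribution()].
#' @param lo,hi Window bounds in micrometres (`lo < hi`).
#' @return Percent of total volume in-window.
#' @export
icc_yield <- function(p, lo = 76, hi = 133) {
  stopifnot(inherits(p, "particle_size_distribution"))
  if (!(lo < hi)) stop_pk("need lo < hi", class = "domain_error")
  if (hi < min(p$center_um) || lo > max(p$center_um)) {
    warn_pk("window [", lo, ", ", hi, "] um lies outside the binned range",
            class = "window_outside_range")
    return(0)
  }
  sum(p$volume_percent[p$center_um >= lo & p$center_um <= hi])
}

# Peak prominences on a smoothed histogram: height above the key saddle
# towards the nearest higher peak (global maximum: height above the global
# minimum).
peak_prominences <- function(y) {
  n <- length(y)
  peaks <- which(diff(sign(diff(c(-Inf, y, -Inf)))) == -2)
  prom <- vapply(peaks, function(i) {
    left <- if (i > 1L) y[1:(i - 1L)] else numeric(0)
    right <- if (i < n) y[(i + 1L):n] else numeric(0)
    saddle_side <- function(side) {
      higher <- which(side > y[i])
      if (!length(higher)) return(min(c(side, y[i])))
      min(side[seq_len(min(higher) - 1L)], y[i])
    }
    lmin <- saddle_side(rev(left))
    rmin <- saddle_side(right)
    y[i] - max(lmin, rmin)
  }, numeric(1))
  list(peaks = peaks, prominence = prom)
}

#' Summary statistics of a particle size distribution
#'
#' Volume-weighted mean size and modality. Modes are local maxima of the
#' 3-bin moving-average smoothed histogram with prominence of at least 5%
#' of the global maximum.
#'
#' @param p A [particle_size_distribution()].
#' @param prominence_frac Minimum mode prominence as a fraction of the
#'   smoothed global maximum (default 0.05).
#' @return List with `volume_weighted_mean_um`, `n_modes` and
#'   `modal_positions_um` (geometric bin centres of the modes).
#' @export
psd_summary <- function(p, prominence_frac = 0.05) {
  stopifnot(inherits(p, "particle_size_distribution"))
  vw_mean <- sum(p$center_um * p$volume_percent) / 100
  sm <- moving_average3(p$volume_percent)
  pr <- peak_prominences(sm)
  keep <- pr$prominence >= prominence_frac * max(sm)
  list(volume_weighted_mean_um = vw_mean,
       n_modes = sum(keep),
       modal_positions_um = p$center_um[pr$peaks[keep]])
}
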