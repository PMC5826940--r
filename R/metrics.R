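# Target-engagement measures: per-ROI peak field magnitude and the
# threshold-based modulated volume of a network side, plus the linear
# current-amplitude sweep and the coefficient of variation across heads.

#' Peak electric field magnitude within an ROI
#'
#' Maximum of `|E|` over the voxels of a mask. A robust upper-percentile
#' variant is available because voxelized corners can carry spurious maxima;
#' it is off by default and the choice is recorded in the returned value's
#' `"definition"` attribute.
#'
#' @param e_mag Numeric 3D `|E|` array (V/m).
#' @param mask Logical array, same shape, non-empty.
#' @param percentile Optional probability (e.g. 0.999) replacing the strict
#'   maximum with an upper quantile.
#' @return Peak field in V/m.
#' @export
peak_field <- function(e_mag, mask, percentile = NULL) {
  stopifnot(is.array(e_mag), identical(dim(e_mag), dim(mask)))
  if (!any(mask)) stop("ROI mask is empty")
  vals <- e_mag[mask]
  if (anyNA(vals)) vals <- vals[!is.na(vals)]
  out <- if (is.null(percentile)) max(vals)
  else stats::quantile(vals, percentile, names = FALSE, type = 7)
  attr(out, "definition") <- if (is.null(percentile)) "max"
  else sprintf("quantile_%g", percentile)
  out
}

#' Threshold-based modulated volume of a network
#'
#' Percentage of a network mask's volume exposed to a field magnitude at or
#' above the modulation threshold: `100 * |{v in mask : E(v)/E_th >= 1}| /
#' |mask|`. The boundary case `E = E_th` counts as modulated. With isotropic
#' voxels the voxel-count ratio equals the volume ratio exactly.
#'
#' @param e_mag Numeric 3D `|E|` array (V/m).
#' @param mask Logical union mask of the network side (overlapping ROIs
#'   counted once), non-empty.
#' @param e_th Modulation threshold in V/m (> 0); default 0.2 V/m, the
#'   commonly reported minimum direct-current field that shifts neuronal
#'   firing in vitro.
#' @return Modulated volume in percent, within `[0, 100]`.
#' @export
modulated_volume <- function(e_mag, mask, e_th = 0.2) {
  stopifnot(is.array(e_mag), identical(dim(e_mag), dim(mask)))
  if (!is.numeric(e_th) || e_th <= 0) stop("E_th must be > 0")
  if (!any(mask)) stop("network union mask is empty")
  vals <- e_mag[mask]
  100 * sum(vals >= e_th, na.rm = TRUE) / length(vals)
}

#' Linear current-amplitude sweep of engagement metrics
#'
#' The quasi-static field scales linearly with the injected current, so a
#' single solve at a reference amplitude yields the whole sweep: peaks scale
#' exactly by `amplitude / reference`, modulated volumes are recomputed on
#' the scaled field (equivalently, against a scaled threshold).
#'
#' @param solution A `field_solution` with `E_mag` present, solved at
#'   `reference_mA`.
#' @param reference_mA Amplitude (mA) at which `solution` was computed.
#' @param rois A `roi_set`.
#' @param amplitudes Amplitudes in mA, strictly increasing and positive;
#'   default the tolerable 1-4 mA range in 0.5 mA steps.
#' @param e_th Modulation threshold, V/m.
#' @return Data frame with columns `amplitude`, `measure`
#'   (`"peak_field"` per ROI / `"modulated_volume"` per side), `target`,
#'   `value`.
#' @export
sweep_currents <- function(solution, reference_mA, rois,
                           amplitudes = seq(1, 4, by = 0.5), e_th = 0.2) {
  if (is.null(solution$E_mag)) stop("solution has no |E|; run compute_field()")
  if (any(amplitudes <= 0)) stop("amplitudes must be positive")
  if (is.unsorted(amplitudes, strictly = TRUE))
    stop("amplitudes must be strictly increasing")
  base_peaks <- vapply(rois$masks, function(m)
    as.numeric(peak_field(solution$E_mag, m)), numeric(1))
  sides <- intersect(c("left", "right"), unique(rois$info$laterality))
  unions <- lapply(sides, function(s) side_union(rois, s))
  names(unions) <- sides
  rows <- lapply(amplitudes, function(a) {
    sc <- a / reference_mA
    rbind(
      data.frame(amplitude = a, measure = "peak_field",
                 target = names(base_peaks), value = sc * base_peaks,
                 stringsAsFactors = FALSE),
      data.frame(amplitude = a, measure = "modulated_volume",
                 target = sides,
                 value = vapply(unions, function(u)
                   modulated_volume(solution$E_mag, u, e_th / sc), numeric(1)),
                 stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean; the
#' dimensionless dispersion measure used to express inter-individual
#' variability of engagement metrics across head models.
#'
#' @param values Numeric vector of at least 2 measurements with nonzero mean.
#' @return CV as a ratio (not percent).
#' @export
#' @examples
#' coefficient_of_variation(c(2, 4))  # 0.4714
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("CV needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CV is undefined for zero mean")
  sd(values) / m
}
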