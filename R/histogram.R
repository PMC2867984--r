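#' 256-bin percentage intensity histogram
#'
#' The distribution of 8-bit signal intensities as a tibble with one row per
#' integer intensity 0-255 and the percentage of pixels in each bin;
#' percentages sum to 100. The pixel count is carried in the `n_pixels`
#' attribute.
#'
#' @param values Integer intensities in `[0, 255]`.
#' @return A tibble of class `intensity_histogram` with columns `intensity`
#'   and `percent`.
#' @examples
#' intensity_histogram(c(0, 0, 5, 255))
#' @export
intensity_histogram <- function(values) {
  v <- as.numeric(values)
  if (length(v) < 1L)
    abort("Need at least one pixel.", class = "lgequant_mask_error")
  if (any(!is.finite(v)) || any(v < 0) || any(v > 255) || any(v != round(v)))
    abort("Intensities must be integers in [0, 255]; convert with to_8bit() first.",
          class = "lgequant_parameter_error")
  counts <- tabulate(v + 1L, nbins = 256L)
  new_intensity_histogram(100 * counts / length(v), n_pixels = length(v))
}

new_intensity_histogram <- function(percent, n_pixels) {
  out <- tibble(intensity = 0:255, percent = as.numeric(percent))
  attr(out, "n_pixels") <- n_pixels
  class(out) <- c("intensity_histogram", class(out))
  out
}

check_histogram <- function(hist) {
  if (!is.data.frame(hist) || !all(c("intensity", "percent") %in% names(hist)) ||
      nrow(hist) != 256L)
    abort("Expected a 256-bin `intensity_histogram` (columns intensity, percent).",
          class = "lgequant_parameter_error")
  if (any(hist$percent < 0))
    abort("Histogram bins must be nonnegative.", class = "lgequant_parameter_error")
  invisible(hist)
}

#' Myocardial intensity histogram
#'
#' Distribution of signal intensity over the whole myocardial mass: bin `i`
#' holds `100 * (# masked pixels with intensity i) / n`.
#'
#' @param image8 An 8-bit [gray_image()].
#' @param mask Logical matrix selecting the myocardial pixels.
#' @return An [intensity_histogram].
#' @export
myocardial_histogram <- function(image8, mask) {
  check_gray_image(image8, "8bit")
  if (!is.matrix(mask) || !is.logical(mask) ||
      !identical(dim(mask), dim(image8$pixels)))
    abort("`mask` must be a logical matrix congruent with the image.",
          class = "lgequant_parameter_error")
  if (!any(mask))
    abort("Mask covers zero pixels.", class = "lgequant_mask_error")
  intensity_histogram(image8$pixels[mask])
}

#' Discretized Rayleigh reference curve
#'
#' The ideal distribution of signal intensity in perfectly nulled myocardium,
#' rendered on the 0-255 integer grid in the same units as a measured
#' histogram: bin `i` holds 100 times the model probability mass in
#' `[i - 0.5, i + 0.5)` (clipped to nonnegative intensities), obtained by
#' per-bin integration of the chi CDF rather than sampling the density at bin
#' centres. For realistic noise levels essentially all mass lies below 255 and
#' the bins sum to 100.
#'
#' @param model A [noise_model()] built from the background-ROI noise level.
#' @param tail_mass Passed to [rc_threshold()] for the saturation check.
#' @param offset Location shift of the curve on the intensity axis (see
#'   [window_offset()]); default 0.
#' @return An [intensity_histogram]-shaped tibble (`n_pixels` attribute `NA`:
#'   it is a model curve, not a pixel count).
#' @examples
#' curve <- rayleigh_reference_curve(noise_model(2.05, 8))
#' curve$intensity[which.max(curve$percent)] # near the mode 2.05 * sqrt(15)
#' @export
rayleigh_reference_curve <- function(model, tail_mass = 1e-4, offset = 0) {
  check_noise_model(model)
  # errors with saturation if the curve overflows 255
  rc_threshold(model, tail_mass, offset = offset)
  hi <- rayleigh_cdf(0:255 + 0.5 - offset, model)
  lo <- c(rayleigh_cdf(-0.5 - offset, model), hi[-256])
  new_intensity_histogram(100 * (hi - lo), n_pixels = NA_integer_)
}

#' Concordance between a measured histogram and the Rayleigh curve
#'
#' The area of the intersection between the measured myocardial distribution
#' and the ideal noise curve, expressed as a percentage of the area under the
#' Rayleigh curve:
#' \deqn{100 \sum_i \min(m_i, r_i) / \sum_i r_i.}
#' Near 100 for normal myocardium; enhancement moves myocardial mass to
#' intensities the noise curve cannot reach and drives the concordance down.
#' Computed bin-wise on the 0-255 integer grid so the statistic is exactly
#' reproducible from the 8-bit pipeline.
#'
#' @param measured An [intensity_histogram] of the myocardium.
#' @param reference A [rayleigh_reference_curve()] on the same grid.
#' @return Concordance in percent, in `[0, 100]`.
#' @export
concordance <- function(measured, reference) {
  check_histogram(measured)
  check_histogram(reference)
  ref_area <- sum(reference$percent)
  if (ref_area <= 0)
    abort("Reference curve has zero area: invalid noise model.",
          class = "lgequant_model_error")
  100 * sum(pmin(measured$percent, reference$percent)) / ref_area
}

#' Overlay plot of measured histogram and Rayleigh reference curve
#'
#' @param measured An [intensity_histogram].
#' @param reference A [rayleigh_reference_curve()].
#' @param xlim Intensity range to display.
#' @return A ggplot object; the shaded region is the intersection area whose
#'   share of the reference area is the concordance.
#' @export
plot_histogram_overlap <- function(measured, reference, xlim = c(0, 60)) {
  check_histogram(measured)
  check_histogram(reference)
  df <- tibble(
    intensity = measured$intensity,
    measured = measured$percent,
    reference = reference$percent,
    intersection = pmin(measured$percent, reference$percent)
  )
  long <- tidyr::pivot_longer(df, c("measured", "reference"),
                              names_to = "curve", values_to = "percent")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$intensity)) +
    ggplot2::geom_area(data = df,
                       ggplot2::aes(y = .data$intersection),
                       fill = "gold", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$percent, colour = .data$curve)) +
    ggplot2::scale_colour_manual(values = c(measured = "#2166AC", reference = "#D6604D")) +
    ggplot2::coord_cartesian(xlim = xlim) +
    ggplot2::labs(x = "signal intensity (8-bit)", y = "% of pixels",
                  colour = NULL,
                  title = sprintf("Concordance %.1f%%", concordance(measured, reference))) +
    ggplot2::theme_minimal()
}

#' Write a histogram or reference curve to CSV
#'
#' @param hist An [intensity_histogram].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(hist, path) {
  check_histogram(hist)
  utils::write.csv(as.data.frame(hist[, c("intensity", "percent")]),
                   path, row.names = FALSE)
  invisible(path)
}
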