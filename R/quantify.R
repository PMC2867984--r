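#' Fixed-cutoff enhancement threshold (nSD method)
#'
#' Threshold for the SD2/SD6 methods: the mean of a visually normal myocardial
#' ROI plus `n_sd` sample standard deviations, kept real-valued.
#'
#' @param myo_roi_pixels Intensities of the normal-myocardium ROI (>= 2).
#' @param n_sd Number of standard deviations above the mean (2 or 6 in the
#'   standard methods; any positive value accepted).
#' @return A single threshold intensity.
#' @examples
#' sd_threshold(c(3, 5, 7), n_sd = 2)
#' @export
sd_threshold <- function(myo_roi_pixels, n_sd) {
  x <- as.numeric(myo_roi_pixels)
  if (length(x) < 2L)
    abort("Myocardial ROI needs at least 2 pixels.", class = "lgequant_roi_error")
  if (!is.numeric(n_sd) || length(n_sd) != 1L || n_sd <= 0)
    abort("`n_sd` must be a single positive number.", class = "lgequant_parameter_error")
  mean(x) + n_sd * sd(x)
}

#' Classify enhanced myocardium by thresholding
#'
#' A pixel is enhanced iff it lies in the myocardium mask and its intensity is
#' strictly greater than the threshold.
#'
#' @param image8 An 8-bit [gray_image()].
#' @param myo_mask Logical myocardium mask.
#' @param threshold Intensity cutoff.
#' @return Logical matrix, a subset of `myo_mask`.
#' @export
classify_enhanced <- function(image8, myo_mask, threshold) {
  check_gray_image(image8, "8bit")
  if (!is.matrix(myo_mask) || !is.logical(myo_mask) ||
      !identical(dim(myo_mask), dim(image8$pixels)))
    abort("`myo_mask` must be a logical matrix congruent with the image.",
          class = "lgequant_parameter_error")
  if (!any(myo_mask))
    abort("Myocardium mask is empty.", class = "lgequant_mask_error")
  myo_mask & (image8$pixels > threshold)
}

#' Extent of enhancement as a percentage of the myocardial mass
#'
#' `100 * |enhanced| / |myocardium|` in pixels. With uniform slice thickness
#' and no gap the pixel-count ratio equals the mass ratio.
#'
#' @param enhanced_mask Logical matrix, subset of `myo_mask`.
#' @param myo_mask Logical nonempty myocardium mask.
#' @return Percentage in `[0, 100]`.
#' @export
extent_percent <- function(enhanced_mask, myo_mask) {
  if (!any(myo_mask))
    abort("Myocardium mask is empty.", class = "lgequant_mask_error")
  if (any(enhanced_mask & !myo_mask))
    abort("Enhanced mask extends outside the myocardium mask.",
          class = "lgequant_mask_error")
  100 * sum(enhanced_mask) / sum(myo_mask)
}

#' Simplified parametric map
#'
#' Label image for visual comparison with the source LGE slice:
#' 0 = outside the left ventricle, 1 = normal myocardium, 2 = enhanced
#' myocardium.
#'
#' @param myo_mask,enhanced_mask Logical matrices, `enhanced_mask` a subset of
#'   `myo_mask`.
#' @return Integer label matrix.
#' @seealso [write_parametric_png()] for the fixed-palette export (enhanced in
#'   pink, normal myocardium in gray).
#' @export
parametric_map <- function(myo_mask, enhanced_mask) {
  if (!identical(dim(myo_mask), dim(enhanced_mask)))
    abort("Masks must be congruent in shape.", class = "lgequant_parameter_error")
  if (any(enhanced_mask & !myo_mask))
    abort("Enhanced mask extends outside the myocardium mask.",
          class = "lgequant_mask_error")
  m <- matrix(0L, nrow(myo_mask), ncol(myo_mask))
  m[myo_mask] <- 1L
  m[enhanced_mask] <- 2L
  m
}

#' Quantify enhancement with the SD2, SD6 and RC methods
#'
#' Runs the three detection methods on one 8-bit slice: SD2 and SD6 threshold
#' at the normal-myocardium ROI mean plus 2 or 6 SD; the RC method builds a
#' [noise_model()] from the background-ROI noise and thresholds at the top of
#' its Rayleigh curve ([rc_threshold()]). Also computes the slice concordance
#' between the measured myocardial histogram and the Rayleigh reference curve.
#'
#' By default the noise level handed to the Rayleigh curve is the
#' moment-corrected background SD (see [estimate_sigma()]): the raw magnitude
#' SD understates the per-channel sigma, and an uncorrected curve would sit
#' below the bulk of the nulled-myocardium distribution. Set
#' `sigma_method = "direct"` to plug the raw background SD in unchanged.
#' Because the min-to-max windowing subtracts the image minimum, the noise
#' distribution in the 8-bit image is a location-shifted chi; with
#' `align_background = TRUE` (default) the shift is estimated from the
#' background ROI mean ([window_offset()]) and the reference curve and RC
#' threshold are aligned with it.
#'
#' @param image8 An 8-bit [gray_image()].
#' @param seg A [segmentation_set()] with a `myocardial_roi`.
#' @param model Optional [noise_model()]; if `NULL` (default), estimated from
#'   the background ROI of `seg`.
#' @param coils Coil count `K` used when estimating the model. Default 8.
#' @param tail_mass Upper-tail mass defining the RC threshold.
#' @param sigma_method `"moment_corrected"` (default) or `"direct"`.
#' @param align_background If `TRUE` (default), shift the reference curve and
#'   RC threshold by the window offset estimated from the background ROI.
#' @param two_band If `TRUE`, additionally report a two-band split of the RC
#'   detection -- "mild" (RC threshold up to the SD6 threshold) and "higher"
#'   (above SD6). This split is an extension, not part of the three standard
#'   methods.
#' @return An `lge_quant` object: list with `results` (tibble: method,
#'   threshold, n_enhanced, extent_percent, enhanced_mask list-column),
#'   `concordance`, `model`, `histogram`, `reference`, `myo_mask`,
#'   `myo_pixel_count`, and optionally `bands`.
#' @export
quantify_all <- function(image8, seg, model = NULL, coils = 8L, tail_mass = 1e-4,
                         sigma_method = c("moment_corrected", "direct"),
                         align_background = TRUE, two_band = FALSE) {
  sigma_method <- match.arg(sigma_method)
  check_gray_image(image8, "8bit")
  myo_mask <- myocardium_mask(seg)
  if (is.null(seg$myocardial_roi) || !any(seg$myocardial_roi))
    abort("Segmentation has no myocardial ROI for the SD methods.",
          class = "lgequant_roi_error")
  bk <- roi_pixels_from_seg(image8, seg)
  if (is.null(model)) {
    model <- noise_model(estimate_sigma(bk, sigma_method, coils = coils),
                         coils = coils)
  } else {
    check_noise_model(model)
  }
  offset <- if (align_background) window_offset(bk, model) else 0

  roi_px <- image8$pixels[seg$myocardial_roi]
  thresholds <- c(SD2 = sd_threshold(roi_px, 2),
                  SD6 = sd_threshold(roi_px, 6),
                  RC = rc_threshold(model, tail_mass, offset = offset))
  masks <- lapply(thresholds, function(t) classify_enhanced(image8, myo_mask, t))
  results <- tibble(
    method = names(thresholds),
    threshold = unname(thresholds),
    n_enhanced = unname(vapply(masks, sum, integer(1))),
    extent_percent = unname(vapply(masks, extent_percent, numeric(1),
                                   myo_mask = myo_mask)),
    enhanced_mask = unname(masks)
  )

  hist <- myocardial_histogram(image8, myo_mask)
  ref <- rayleigh_reference_curve(model, tail_mass, offset = offset)
  out <- list(results = results,
              concordance = concordance(hist, ref),
              model = model,
              offset = offset,
              histogram = hist,
              reference = ref,
              myo_mask = myo_mask,
              myo_pixel_count = sum(myo_mask))
  if (two_band) {
    mild <- masks$RC & !masks$SD6
    out$bands <- tibble(
      band = c("mild", "higher"),
      extent_percent = c(extent_percent(mild, myo_mask),
                         extent_percent(masks$SD6 & masks$RC, myo_mask))
    )
  }
  structure(out, class = "lge_quant")
}

#' @export
print.lge_quant <- function(x, ...) {
  cat(sprintf("<lge_quant> %d myocardial pixels, concordance %.1f%%\n",
              x$myo_pixel_count, x$concordance))
  print(dplyr::select(x$results, -"enhanced_mask"))
  invisible(x)
}

#' @rdname quantify_all
#' @param x An `lge_quant` object.
#' @param ... Unused.
#' @method tidy lge_quant
#' @export
tidy.lge_quant <- function(x, ...) {
  dplyr::select(x$results, "method", "threshold", "n_enhanced", "extent_percent")
}

#' @rdname quantify_all
#' @method glance lge_quant
#' @export
glance.lge_quant <- function(x, ...) {
  tibble(concordance = x$concordance,
         sigma = x$model$sigma,
         coils = x$model$coils,
         myo_pixel_count = x$myo_pixel_count)
}

#' @rdname quantify_all
#' @param object An `lge_quant` object.
#' @param method Which method's parametric map to draw.
#' @method autoplot lge_quant
#' @export
autoplot.lge_quant <- function(object, method = "RC", ...) {
  row <- dplyr::filter(object$results, .data$method == !!method)
  if (nrow(row) != 1L)
    abort(sprintf("Unknown method '%s'.", method), class = "lgequant_parameter_error")
  map <- parametric_map(object$myo_mask, row$enhanced_mask[[1]])
  df <- tibble(
    row = as.vector(base::row(map)),
    col = as.vector(base::col(map)),
    tissue = factor(as.vector(map), levels = 0:2,
                    labels = c("outside LV", "normal myocardium", "enhanced"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$tissue)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c("outside LV" = "black",
                                          "normal myocardium" = "gray60",
                                          "enhanced" = "#FF69B4")) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s method: extent %.1f%% of myocardium",
                                  method, row$extent_percent),
                  x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}

#' Quantify a simulated cohort
#'
#' Runs [quantify_all()] on every subject of a [simulate_cohort()] table and
#' returns one tidy row per subject and method, ready for the ROC analysis of
#' the concordance statistic.
#'
#' @param cohort Tibble from [simulate_cohort()].
#' @param ... Passed to [quantify_all()] (e.g. `tail_mass`, `sigma_method`).
#' @return A tibble with columns `subject_id`, `group`, `true_fraction`,
#'   `method`, `threshold`, `extent_percent`, `concordance`.
#' @export
quantify_cohort <- function(cohort, ...) {
  if (!is.data.frame(cohort) || !all(c("subject_id", "group", "image", "seg") %in% names(cohort)))
    abort("`cohort` must come from simulate_cohort().", class = "lgequant_parameter_error")
  purrr::pmap_dfr(
    list(cohort$subject_id, cohort$group, cohort$true_fraction,
         cohort$image, cohort$seg),
    function(id, grp, truef, img, seg) {
      q <- quantify_all(to_8bit(img), seg, ...)
      dplyr::mutate(tidy(q),
                    subject_id = id, group = grp, true_fraction = truef,
                    concordance = q$concordance,
                    .before = 1)
    })
}
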