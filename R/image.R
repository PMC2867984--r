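#' Grayscale magnitude image with pixel spacing
#'
#' A thin container pairing a 2-D nonnegative pixel matrix with its physical
#' pixel spacing. `bit_depth = "raw"` holds arbitrary nonnegative intensities
#' as reconstructed; `"8bit"` holds integers in 0-255 after min-to-max
#' windowing ([to_8bit()]).
#'
#' @param pixels Numeric matrix of nonnegative intensities.
#' @param pixel_spacing_mm Pixel spacing in mm: length 1 (square pixels) or 2
#'   `(row, col)`.
#' @param bit_depth `"raw"` or `"8bit"`.
#' @return A `gray_image` object.
#' @export
gray_image <- function(pixels, pixel_spacing_mm, bit_depth = c("raw", "8bit")) {
  bit_depth <- match.arg(bit_depth)
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) < 1L)
    abort("`pixels` must be a nonempty numeric matrix.", class = "lgequant_parameter_error")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    abort("Pixel intensities must be finite and nonnegative.",
          class = "lgequant_parameter_error")
  sp <- as.numeric(pixel_spacing_mm)
  if (length(sp) == 1L) sp <- c(sp, sp)
  if (length(sp) != 2L || any(!is.finite(sp)) || any(sp <= 0))
    abort("`pixel_spacing_mm` must be 1 or 2 positive values.",
          class = "lgequant_parameter_error")
  if (bit_depth == "8bit" &&
      (any(pixels != round(pixels)) || max(pixels) > 255))
    abort("8-bit images must contain integers in [0, 255].",
          class = "lgequant_parameter_error")
  structure(list(pixels = pixels, pixel_spacing_mm = sp, bit_depth = bit_depth),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %.4g x %.4g mm/px, %s (range %.4g-%.4g)\n",
              nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2], x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

check_gray_image <- function(image, bit_depth = NULL) {
  if (!inherits(image, "gray_image"))
    abort("Expected a `gray_image` object.", class = "lgequant_parameter_error")
  if (!is.null(bit_depth) && image$bit_depth != bit_depth)
    abort(sprintf("Expected a %s image, got %s.", bit_depth, image$bit_depth),
          class = "lgequant_parameter_error")
  invisible(image)
}

#' Convert a raw image to the fixed 0-255 grayscale
#'
#' Fixed minimum-to-maximum windowing: an affine map sending the image minimum
#' to 0 and maximum to 255, rounded half-up to integers. Order-preserving, and
#' invariant under any positive affine rescaling of the raw intensities, so
#' acquisition windowing differences are nulled. A constant image has no
#' window; it maps to all zeros with a warning.
#'
#' @param image A raw [gray_image()].
#' @return An 8-bit `gray_image` of the same shape and spacing.
#' @examples
#' img <- gray_image(matrix(c(10, 20, 30, 40), 2), 1)
#' to_8bit(img)$pixels
#' @export
to_8bit <- function(image) {
  check_gray_image(image)
  px <- image$pixels
  rng <- max(px) - min(px)
  out <- if (rng == 0) {
    warn("Constant image: min-to-max window is degenerate, mapping all pixels to 0.",
         class = "lgequant_constant_image_warning")
    array(0, dim = dim(px))
  } else {
    floor((px - min(px)) / rng * 255 + 0.5)  # round half-up
  }
  gray_image(out, image$pixel_spacing_mm, bit_depth = "8bit")
}

#' Segmentation set: contours and ROIs for one short-axis slice
#'
#' Holds the manually traced endocardial and epicardial contours as filled
#' boolean masks, the background ROI box (pure noise, placed near the thoracic
#' wall away from the anatomy), and a normal-myocardium ROI used by the
#' fixed-cutoff SD methods.
#'
#' @param endo_mask,epi_mask Logical matrices, same shape as the image; every
#'   endocardial pixel must lie inside the epicardial contour.
#' @param background_roi A list or numeric vector `(row, col, side_mm)`: the
#'   top-left pixel anchor and physical side of a square background box. Must
#'   not overlap the epicardial mask.
#' @param myocardial_roi Logical matrix marking a visually normal myocardial
#'   region (subset of the myocardium), or `NULL` to fill in later.
#' @return A `segmentation_set` object.
#' @export
segmentation_set <- function(endo_mask, epi_mask, background_roi,
                             myocardial_roi = NULL) {
  for (m in list(endo_mask, epi_mask))
    if (!is.matrix(m) || !is.logical(m))
      abort("Masks must be logical matrices.", class = "lgequant_parameter_error")
  if (!identical(dim(endo_mask), dim(epi_mask)))
    abort("Masks must be congruent in shape.", class = "lgequant_parameter_error")
  if (any(endo_mask & !epi_mask))
    abort("Endocardial contour extends outside the epicardial contour.",
          class = "lgequant_contour_error")
  bk <- as.numeric(unlist(background_roi[c(1, 2, 3)]))
  if (length(bk) != 3L || any(!is.finite(bk)) || bk[3] <= 0)
    abort("`background_roi` must be (row, col, side_mm) with side_mm > 0.",
          class = "lgequant_parameter_error")
  if (!is.null(myocardial_roi)) {
    if (!is.matrix(myocardial_roi) || !is.logical(myocardial_roi) ||
        !identical(dim(myocardial_roi), dim(epi_mask)))
      abort("`myocardial_roi` must be a logical matrix congruent with the masks.",
            class = "lgequant_parameter_error")
  }
  structure(list(endo_mask = endo_mask, epi_mask = epi_mask,
                 background_roi = list(row = bk[1], col = bk[2], side_mm = bk[3]),
                 myocardial_roi = myocardial_roi),
            class = "segmentation_set")
}

#' Left-ventricular myocardium mask
#'
#' The myocardium is the set difference between the filled epicardial and
#' endocardial contours (the annulus between the two traced borders).
#'
#' @param seg A [segmentation_set()].
#' @return A logical matrix.
#' @export
myocardium_mask <- function(seg) {
  if (!inherits(seg, "segmentation_set"))
    abort("`seg` must be a `segmentation_set`.", class = "lgequant_parameter_error")
  m <- seg$epi_mask & !seg$endo_mask
  if (!any(m))
    abort("Myocardium mask is empty: check the traced contours.",
          class = "lgequant_contour_error")
  m
}

#' Extract the pixels of a square physical ROI
#'
#' Converts a square box given in millimetres to pixels using the image spacing
#' (`side_px = round(side_mm / spacing)` per axis) and returns the enclosed
#' intensities. The reference protocol's 25 x 25 mm background box on a 400 mm
#' field of view with a 256-pixel matrix encloses 16 x 16 = 256 pixels.
#'
#' @param image A [gray_image()].
#' @param box_mm Side of the square box in mm.
#' @param anchor Top-left pixel position `(row, col)` of the box.
#' @return Numeric vector of the enclosed pixel intensities.
#' @export
box_to_roi_pixels <- function(image, box_mm, anchor) {
  check_gray_image(image)
  if (!is.numeric(box_mm) || length(box_mm) != 1L || box_mm <= 0)
    abort("`box_mm` must be a single positive number.", class = "lgequant_parameter_error")
  a <- as.integer(round(anchor))
  side <- pmax(1L, as.integer(round(box_mm / image$pixel_spacing_mm)))
  r2 <- a[1] + side[1] - 1L
  c2 <- a[2] + side[2] - 1L
  if (length(a) != 2L || any(a < 1L) || r2 > nrow(image$pixels) || c2 > ncol(image$pixels))
    abort(sprintf("ROI box [%d:%d, %d:%d] falls outside the %d x %d image.",
                  a[1], r2, a[2], c2, nrow(image$pixels), ncol(image$pixels)),
          class = "lgequant_geometry_error")
  as.numeric(image$pixels[a[1]:r2, a[2]:c2])
}

roi_pixels_from_seg <- function(image, seg) {
  bk <- seg$background_roi
  box_to_roi_pixels(image, bk$side_mm, c(bk$row, bk$col))
}

#' Contrast-to-noise ratio between myocardium and background
#'
#' `CNR = 2 (mean_myo - mean_bk) / (SD_myo + SD_bk)`, a check of nulling
#' quality: for perfectly nulled myocardium both ROIs sample the same noise
#' process, the means coincide and the formula gives approximately 0. (The
#' complementary ratio of means, which tends to 1 in that situation, is
#' available as [nulling_ratio()].)
#'
#' @param myo_pixels,bk_pixels Numeric vectors of ROI intensities (>= 2 each).
#' @return A single ratio.
#' @examples
#' cnr(c(8, 10, 12), c(4, 6, 8))
#' @export
cnr <- function(myo_pixels, bk_pixels) {
  if (length(myo_pixels) < 2L || length(bk_pixels) < 2L)
    abort("Both ROIs need at least 2 pixels.", class = "lgequant_roi_error")
  denom <- sd(myo_pixels) + sd(bk_pixels)
  if (denom == 0)
    abort("Both ROIs are constant-valued: CNR undefined.",
          class = "lgequant_degenerate_roi_error")
  2 * (mean(myo_pixels) - mean(bk_pixels)) / denom
}

#' Mean-intensity ratio of myocardium to background
#'
#' For perfectly nulled myocardium the signal in the myocardium is pure noise
#' drawn from the same process as the background, so this ratio tends to 1.
#'
#' @inheritParams cnr
#' @return `mean(myo_pixels) / mean(bk_pixels)`.
#' @export
nulling_ratio <- function(myo_pixels, bk_pixels) {
  if (length(myo_pixels) < 1L || length(bk_pixels) < 1L)
    abort("Both ROIs must be nonempty.", class = "lgequant_roi_error")
  mb <- mean(bk_pixels)
  if (mb == 0)
    abort("Background mean is zero: ratio undefined.",
          class = "lgequant_degenerate_roi_error")
  mean(myo_pixels) / mb
}
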