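#' Lesion descriptors for the phantom simulator
#'
#' Lesions live inside the myocardial annulus and carry a true signal
#' amplitude expressed in multiples of the chi model's sigma (the per-channel
#' noise SD), the natural contrast unit of the noise model.
#'
#' `lesion_disc()` is a disc at an offset from the annulus centre;
#' `lesion_wedge()` is an angular sector of the annulus, which makes the
#' enhanced fraction of the myocardium exactly controllable
#' (`fraction = width / (2 * pi)` up to pixelation).
#'
#' @param center_offset_mm Disc centre offset `(row, col)` from the annulus
#'   centre, mm.
#' @param radius_mm Disc radius, mm.
#' @param contrast True signal amplitude in multiples of the per-channel noise
#'   SD (the noise model's sigma).
#' @return A `lesion` list understood by [simulate_image()].
#' @export
lesion_disc <- function(center_offset_mm, radius_mm, contrast) {
  if (radius_mm <= 0 || contrast < 0)
    abort("Disc lesion needs radius_mm > 0 and contrast >= 0.",
          class = "lgequant_spec_error")
  structure(list(shape = "disc", center_offset_mm = as.numeric(center_offset_mm),
                 radius_mm = radius_mm, contrast = contrast),
            class = "lesion")
}

#' @rdname lesion_disc
#' @param theta_start Start angle of the wedge, radians.
#' @param width Angular width of the wedge, radians, in `(0, 2 * pi]`.
#' @export
lesion_wedge <- function(theta_start, width, contrast) {
  if (width <= 0 || width > 2 * pi || contrast < 0)
    abort("Wedge lesion needs width in (0, 2*pi] and contrast >= 0.",
          class = "lgequant_spec_error")
  structure(list(shape = "wedge", theta_start = theta_start, width = width,
                 contrast = contrast),
            class = "lesion")
}

#' Phantom specification for the K-coil magnitude image simulator
#'
#' Describes a synthetic short-axis slice: a myocardial annulus around a
#' bright blood pool on a noise-only background, imaged through `coils`
#' phased-array channels combined by root-sum-of-squares. `sigma` is the
#' target standard deviation of the *background magnitude* (the quantity a
#' background ROI measures); the simulator derives the per-channel noise from
#' it. The default bright blood amplitude of 250 raw units makes the min-to-max
#' 8-bit windowing close to the identity, so the 8-bit background SD lands near
#' the configured `sigma` -- the regime of the reference acquisition
#' (background SD about 2.05 with K = 8).
#'
#' @param image_shape `(rows, cols)` in pixels.
#' @param pixel_spacing_mm Pixel spacing (mm); default 1.5625 = 400 mm field of
#'   view over a 256 reconstruction matrix.
#' @param sigma Target background magnitude SD (raw units). Default 2.05.
#' @param coils Coil count `K`. Default 8.
#' @param endo_radius_mm,epi_radius_mm Endocardial and epicardial radii, mm.
#' @param center_mm Annulus centre `(row, col)` in mm; default the image centre.
#' @param lesions List of [lesion_disc()] / [lesion_wedge()] objects.
#' @param myo_true_signal Residual amplitude of imperfectly nulled myocardium,
#'   in multiples of the per-channel noise SD (0 = perfect nulling).
#' @param blood_signal Blood-pool amplitude in raw units.
#' @param background_side_mm Side of the background ROI box, mm. Default 25.
#' @param seed RNG seed for [simulate_image()]; `NULL` leaves the RNG state
#'   alone.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(image_shape = c(256L, 256L),
                         pixel_spacing_mm = 1.5625,
                         sigma = 2.05,
                         coils = 8L,
                         endo_radius_mm = 20,
                         epi_radius_mm = 32,
                         center_mm = NULL,
                         lesions = list(),
                         myo_true_signal = 0,
                         blood_signal = 250,
                         background_side_mm = 25,
                         seed = NULL) {
  if (sigma <= 0 || coils < 1 || myo_true_signal < 0 || blood_signal < 0)
    abort("Require sigma > 0, coils >= 1, nonnegative amplitudes.",
          class = "lgequant_spec_error")
  if (endo_radius_mm <= 0 || epi_radius_mm <= endo_radius_mm)
    abort("Require 0 < endo_radius_mm < epi_radius_mm.",
          class = "lgequant_spec_error")
  if (!all(vapply(lesions, inherits, logical(1), "lesion")))
    abort("`lesions` must be a list of lesion objects.", class = "lgequant_spec_error")
  sp <- as.numeric(pixel_spacing_mm)
  if (length(sp) == 1L) sp <- c(sp, sp)
  shape <- as.integer(image_shape)
  if (is.null(center_mm)) center_mm <- shape * sp / 2
  structure(list(image_shape = shape, pixel_spacing_mm = sp, sigma = sigma,
                 coils = as.integer(coils), endo_radius_mm = endo_radius_mm,
                 epi_radius_mm = epi_radius_mm, center_mm = as.numeric(center_mm),
                 lesions = lesions, myo_true_signal = myo_true_signal,
                 blood_signal = blood_signal,
                 background_side_mm = background_side_mm, seed = seed),
            class = "phantom_spec")
}

#' Simulate one K-coil magnitude image with ground truth
#'
#' Each pixel is the root-sum-of-squares of `K` complex channels; channel `k`
#' carries `amplitude / sqrt(K)` of true signal on its real part plus
#' independent Gaussian noise on both parts. Background pixels therefore
#' follow the [noise_model()] chi distribution exactly, and lesion pixels its
#' noncentral analogue. The per-channel noise is calibrated so the background
#' *magnitude* SD equals `spec$sigma`, keeping the "SD of the background ROI"
#' convention the ground truth.
#'
#' The background ROI box is placed in the top-left corner, guaranteed
#' lesion-free and disjoint from the epicardial contour; the normal-myocardium
#' ROI is the lesion-free part of the annulus.
#'
#' @param spec A [phantom_spec()].
#' @return An `lge_phantom`: list with `image` (raw [gray_image()]), `seg`
#'   ([segmentation_set()]), `truth` (logical ground-truth enhanced mask) and
#'   `spec`.
#' @examples
#' ph <- simulate_image(phantom_spec(image_shape = c(128, 128), seed = 1))
#' range(ph$image$pixels)
#' @export
simulate_image <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    abort("`spec` must be a `phantom_spec`.", class = "lgequant_spec_error")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  row_mm <- (seq_len(nr) - 0.5) * spec$pixel_spacing_mm[1]
  col_mm <- (seq_len(nc) - 0.5) * spec$pixel_spacing_mm[2]
  dr <- outer(row_mm - spec$center_mm[1], rep(1, nc))
  dc <- outer(rep(1, nr), col_mm - spec$center_mm[2])
  dist <- sqrt(dr^2 + dc^2)
  theta <- atan2(dc, dr) %% (2 * pi)

  endo <- dist < spec$endo_radius_mm
  epi <- dist < spec$epi_radius_mm
  annulus <- epi & !endo

  K <- spec$coils
  sigma_channel <- spec$sigma / chi_sd_factor(K)
  amplitude <- matrix(0, nr, nc)
  amplitude[endo] <- spec$blood_signal
  amplitude[annulus] <- spec$myo_true_signal * sigma_channel
  truth <- matrix(FALSE, nr, nc)
  for (les in spec$lesions) {
    in_les <- if (les$shape == "disc") {
      ctr <- spec$center_mm + les$center_offset_mm
      sqrt((dr - les$center_offset_mm[1])^2 + (dc - les$center_offset_mm[2])^2) <
        les$radius_mm
    } else {
      rel <- (theta - les$theta_start) %% (2 * pi)
      annulus & rel < les$width
    }
    if (les$shape == "disc" && any(in_les & !annulus))
      abort("Lesion extends outside the myocardial annulus.",
            class = "lgequant_spec_error")
    if (les$contrast > 0) {
      amplitude[in_les] <- les$contrast * sigma_channel
      truth <- truth | in_les
    }
  }

  n <- nr * nc
  re <- matrix(rnorm(n * K, sd = sigma_channel), nrow = n) +
    as.vector(amplitude) / sqrt(K)
  im <- matrix(rnorm(n * K, sd = sigma_channel), nrow = n)
  pixels <- matrix(sqrt(rowSums(re^2) + rowSums(im^2)), nr, nc)

  side_px <- pmax(1L, as.integer(round(spec$background_side_mm / spec$pixel_spacing_mm)))
  anchor <- c(2L, 2L)
  box_rows <- anchor[1]:(anchor[1] + side_px[1] - 1L)
  box_cols <- anchor[2]:(anchor[2] + side_px[2] - 1L)
  if (max(box_rows) > nr || max(box_cols) > nc)
    abort("Background box does not fit inside the image.",
          class = "lgequant_spec_error")
  if (any(epi[box_rows, box_cols]) || any(truth[box_rows, box_cols]))
    abort("Background box overlaps the anatomy: enlarge the image or shrink the annulus.",
          class = "lgequant_spec_error")

  seg <- segmentation_set(endo, epi,
                          c(anchor[1], anchor[2], spec$background_side_mm),
                          myocardial_roi = annulus & !truth)
  structure(list(image = gray_image(pixels, spec$pixel_spacing_mm, "raw"),
                 seg = seg, truth = truth, spec = spec),
            class = "lge_phantom")
}

#' Simulate a cohort of diseased and normal subjects
#'
#' Negatives are noise-only phantoms with perfectly nulled myocardium;
#' positives carry a wedge lesion occupying a fraction of the annulus drawn
#' uniformly from `enhancement_range`, at a contrast drawn uniformly from
#' `contrast_range` (in multiples of the background SD). Defaults emulate the
#' reference study design: 40 diseased and 20 normal subjects, enhanced
#' fractions of 20-40% at contrasts of 8-12 SD, K = 8 coils and background SD
#' 2.05 on a 256 x 256 grid at 1.5625 mm/pixel.
#'
#' @param n_positive,n_negative Subject counts (each >= 1).
#' @param enhancement_range Interval of enhanced myocardial fractions for
#'   positives, in `(0, 1)`.
#' @param contrast_range Interval of lesion contrasts (multiples of the
#'   per-channel noise SD).
#' @param seed Master seed; per-subject seeds are drawn from it, so a fixed
#'   seed reproduces the cohort exactly.
#' @param ... Passed on to [phantom_spec()] (e.g. `image_shape`, `sigma`,
#'   `coils`, radii).
#' @return A tibble with one row per subject: `subject_id`, `group`
#'   (`"positive"`/`"negative"`), `target_fraction`, `true_fraction` (realized
#'   pixel fraction), `contrast`, `seed`, and list-columns `image`, `seg`,
#'   `truth`.
#' @export
simulate_cohort <- function(n_positive = 40L, n_negative = 20L,
                            enhancement_range = c(0.20, 0.40),
                            contrast_range = c(8, 12),
                            seed = NULL, ...) {
  if (n_positive < 1L || n_negative < 1L)
    abort("Cohort needs at least one subject per group.",
          class = "lgequant_spec_error")
  for (rng in list(enhancement_range, contrast_range))
    if (length(rng) != 2L || any(!is.finite(rng)) || rng[1] > rng[2])
      abort("Ranges must be finite (lo, hi) intervals with lo <= hi.",
            class = "lgequant_spec_error")
  if (enhancement_range[1] <= 0 || enhancement_range[2] >= 1)
    abort("`enhancement_range` must lie strictly inside (0, 1).",
          class = "lgequant_spec_error")
  if (!is.null(seed)) set.seed(seed)
  n <- n_positive + n_negative
  subj_seed <- sample.int(2^31 - 2, n)
  frac <- c(stats::runif(n_positive, enhancement_range[1], enhancement_range[2]),
            rep(0, n_negative))
  contr <- c(stats::runif(n_positive, contrast_range[1], contrast_range[2]),
             rep(NA_real_, n_negative))
  start <- c(stats::runif(n_positive, 0, 2 * pi), rep(NA_real_, n_negative))
  group <- rep(c("positive", "negative"), c(n_positive, n_negative))

  subjects <- purrr::map(seq_len(n), function(i) {
    lesions <- if (group[i] == "positive")
      list(lesion_wedge(start[i], frac[i] * 2 * pi, contr[i]))
    else list()
    simulate_image(phantom_spec(lesions = lesions, seed = subj_seed[i], ...))
  })
  tibble(
    subject_id = sprintf("%s%02d", ifelse(group == "positive", "hcm", "ctl"),
                         c(seq_len(n_positive), seq_len(n_negative))),
    group = group,
    target_fraction = frac,
    true_fraction = vapply(subjects, function(s)
      sum(s$truth) / sum(myocardium_mask(s$seg)), numeric(1)),
    contrast = contr,
    seed = subj_seed,
    image = purrr::map(subjects, "image"),
    seg = purrr::map(subjects, "seg"),
    truth = purrr::map(subjects, "truth")
  )
}
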