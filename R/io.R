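#' Read a magnitude image from disk
#'
#' Reads a plain numeric-array file (CSV/TSV/TXT, one row per image row) into a
#' raw [gray_image()]. Pixel spacing comes from the `pixel_spacing_mm` argument
#' or, if that is `NULL`, from a YAML sidecar `<path>.yaml` containing a
#' `pixel_spacing_mm` entry. Negative values (e.g. left over from a signed
#' rescale) are clamped to 0 with a warning, since magnitude images are
#' nonnegative. DICOM input is not supported by this reader; export the pixel
#' array to a plain-text matrix first.
#'
#' @param path Path to the array file.
#' @param pixel_spacing_mm Optional spacing override (length 1 or 2, mm).
#' @return A raw [gray_image()].
#' @export
read_image <- function(path, pixel_spacing_mm = NULL) {
  if (!file.exists(path))
    abort(sprintf("Cannot read image file '%s'.", path), class = "lgequant_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom"))
    abort("DICOM input is not supported: export the pixel array to CSV/TSV with a spacing sidecar.",
          class = "lgequant_io_error")
  sep <- if (ext %in% c("tsv", "txt")) "\t" else ","
  px <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(px) <- NULL
  if (!is.numeric(px))
    abort(sprintf("'%s' does not contain a numeric array.", path),
          class = "lgequant_io_error")
  if (any(px < 0)) {
    warn("Negative pixel values clamped to 0 (magnitude images are nonnegative).",
         class = "lgequant_clamp_warning")
    px[px < 0] <- 0
  }
  if (is.null(pixel_spacing_mm)) {
    sidecar <- paste0(path, ".yaml")
    if (!file.exists(sidecar))
      abort(sprintf("No pixel spacing given and no sidecar '%s' found.", sidecar),
            class = "lgequant_metadata_error")
    meta <- yaml::read_yaml(sidecar)
    if (is.null(meta$pixel_spacing_mm))
      abort(sprintf("Sidecar '%s' lacks a `pixel_spacing_mm` entry.", sidecar),
            class = "lgequant_metadata_error")
    pixel_spacing_mm <- as.numeric(meta$pixel_spacing_mm)
  }
  gray_image(px, pixel_spacing_mm, "raw")
}

#' Read a binary mask
#'
#' PNG masks treat any nonzero gray value as inside; CSV/TSV masks expect a
#' 0/1 (or logical) matrix.
#'
#' @param path Path to a PNG or CSV/TSV file.
#' @return A logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path))
    abort(sprintf("Cannot read mask file '%s'.", path), class = "lgequant_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L) arr <- arr[, , 1]
    return(arr > 0)
  }
  sep <- if (ext %in% c("tsv", "txt")) "\t" else ","
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(m) <- NULL
  m > 0
}

#' Write a mask as an 8-bit PNG
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

# Fixed 3-color palette: outside LV black, normal myocardium gray, enhanced pink
map_palette <- function() {
  rbind(`0` = c(0, 0, 0), `1` = c(0.6, 0.6, 0.6), `2` = c(1, 80 / 255, 160 / 255))
}

#' Write a parametric map as a color PNG
#'
#' Renders the 0/1/2 label image from [parametric_map()] with a fixed palette:
#' black outside the left ventricle, gray for normal myocardium, pink for
#' enhanced myocardium.
#'
#' @param map Integer label matrix with values in `{0, 1, 2}`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parametric_png <- function(map, path) {
  if (!all(map %in% 0:2))
    abort("Parametric map labels must be 0, 1 or 2.", class = "lgequant_parameter_error")
  pal <- map_palette()
  rgb <- array(0, dim = c(nrow(map), ncol(map), 3))
  for (ch in 1:3)
    rgb[, , ch] <- matrix(pal[map + 1L, ch], nrow(map), ncol(map))
  png::writePNG(rgb, path)
  invisible(path)
}

#' Run configuration for the quantification pipeline
#'
#' Bundles the inputs and options of one [run_quantify()] call. Either a
#' phantom is simulated (`phantom = TRUE`) or image and mask files are read
#' from disk.
#'
#' @param output_dir Directory for reports (created if missing).
#' @param phantom If `TRUE`, simulate the input with [phantom_spec()] settings
#'   given in `phantom_args`.
#' @param phantom_args List of [phantom_spec()] arguments.
#' @param image,endo_mask,epi_mask,myo_roi_mask File paths (used when
#'   `phantom = FALSE`).
#' @param pixel_spacing_mm Spacing override for [read_image()].
#' @param background_roi `(row, col, side_mm)` background box (file mode).
#' @param methods Methods to report; subset of `c("SD2", "SD6", "RC")`.
#' @param coils,tail_mass,sigma_method Passed to [quantify_all()].
#' @param seed Seed for any simulation in the run.
#' @return A `run_config` list.
#' @export
run_config <- function(output_dir,
                       phantom = FALSE, phantom_args = list(),
                       image = NULL, endo_mask = NULL, epi_mask = NULL,
                       myo_roi_mask = NULL, pixel_spacing_mm = NULL,
                       background_roi = NULL,
                       methods = c("SD2", "SD6", "RC"),
                       coils = 8L, tail_mass = 1e-4,
                       sigma_method = "moment_corrected",
                       seed = NULL) {
  if (!all(methods %in% c("SD2", "SD6", "RC")) || length(methods) < 1L)
    abort("`methods` must be a nonempty subset of SD2, SD6, RC.",
          class = "lgequant_parameter_error")
  if (coils < 1 || tail_mass <= 0 || tail_mass >= 0.5)
    abort("Require coils >= 1 and tail_mass in (0, 0.5).",
          class = "lgequant_parameter_error")
  structure(list(output_dir = output_dir, phantom = phantom,
                 phantom_args = phantom_args, image = image,
                 endo_mask = endo_mask, epi_mask = epi_mask,
                 myo_roi_mask = myo_roi_mask,
                 pixel_spacing_mm = pixel_spacing_mm,
                 background_roi = background_roi, methods = methods,
                 coils = as.integer(coils), tail_mass = tail_mass,
                 sigma_method = sigma_method, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    abort(sprintf("Config file '%s' not found.", path), class = "lgequant_io_error")
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the quantification pipeline end to end
#'
#' Loads (or simulates) one slice, applies the 8-bit conversion, runs
#' [quantify_all()], and writes `results.csv` (method, threshold, extent,
#' concordance), one parametric-map PNG per method, the measured and reference
#' histograms as CSV, and `run.json` with the package version, seed and a
#' config echo. Deterministic for a fixed seed and inputs.
#'
#' @param config A [run_config()] (or path to its YAML file).
#' @return The results tibble, invisibly; files under `config$output_dir`.
#' @export
run_quantify <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config"))
    abort("`config` must be a `run_config` or a YAML path.",
          class = "lgequant_parameter_error")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  if (isTRUE(config$phantom)) {
    args <- config$phantom_args
    if (!is.null(config$seed) && is.null(args$seed)) args$seed <- config$seed
    if (!is.null(args$lesions))
      args$lesions <- lapply(args$lesions, function(l)
        if (inherits(l, "lesion")) l else lesion_from_list(l))
    ph <- simulate_image(do.call(phantom_spec, args))
    image_raw <- ph$image
    seg <- ph$seg
  } else {
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e)
        abort(sprintf("Stage %s failed: %s", what, conditionMessage(e)),
              class = "lgequant_stage_error"))
    }
    image_raw <- stage("cli_io", read_image(config$image, config$pixel_spacing_mm))
    endo <- stage("image_prep", read_mask(config$endo_mask))
    epi <- stage("image_prep", read_mask(config$epi_mask))
    myo_roi <- if (!is.null(config$myo_roi_mask))
      stage("image_prep", read_mask(config$myo_roi_mask)) else NULL
    if (is.null(config$background_roi))
      abort("File-mode config needs a `background_roi` (row, col, side_mm).",
            class = "lgequant_parameter_error")
    seg <- stage("image_prep",
                 segmentation_set(endo, epi, config$background_roi, myo_roi))
  }

  image8 <- to_8bit(image_raw)
  q <- quantify_all(image8, seg, coils = config$coils,
                    tail_mass = config$tail_mass,
                    sigma_method = config$sigma_method)
  results <- dplyr::mutate(
    dplyr::filter(tidy(q), .data$method %in% config$methods),
    concordance = q$concordance, sigma = q$model$sigma)

  utils::write.csv(as.data.frame(results),
                   file.path(config$output_dir, "results.csv"), row.names = FALSE)
  for (m in config$methods) {
    em <- q$results$enhanced_mask[[match(m, q$results$method)]]
    write_parametric_png(parametric_map(q$myo_mask, em),
                         file.path(config$output_dir, sprintf("map_%s.png", m)))
  }
  write_histogram_csv(q$histogram, file.path(config$output_dir, "histogram_measured.csv"))
  write_histogram_csv(q$reference, file.path(config$output_dir, "histogram_rayleigh.csv"))
  meta <- list(package = "lgequant",
               version = as.character(utils::packageVersion("lgequant")),
               seed = config$seed,
               config = config[setdiff(names(config), c("phantom_args"))],
               thresholds = stats::setNames(as.list(results$threshold), results$method))
  jsonlite::write_json(meta, file.path(config$output_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(results)
}

# rebuild a lesion object from a plain YAML list
lesion_from_list <- function(l) {
  if (identical(l$shape, "disc"))
    lesion_disc(unlist(l$center_offset_mm), l$radius_mm, l$contrast)
  else
    lesion_wedge(l$theta_start, l$width, l$contrast)
}
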