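test_that("simulation is deterministic under a fixed seed", {
  s <- phantom_spec(image_shape = c(64L, 64L), pixel_spacing_mm = 1,
                    endo_radius_mm = 10, epi_radius_mm = 16,
                    background_side_mm = 8, seed = 123)
  a <- simulate_image(s)
  b <- simulate_image(s)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)
})

test_that("background magnitude moments match the closed-form chi moments", {
  # big noise-only field: a tiny annulus far in a corner leaves >1e5 background px
  s <- phantom_spec(image_shape = c(360L, 360L), pixel_spacing_mm = 1,
                    sigma = 2.05, coils = 8,
                    endo_radius_mm = 10, epi_radius_mm = 16,
                    center_mm = c(300, 300), blood_signal = 250, seed = 77)
  ph <- simulate_image(s)
  bg <- !ph$seg$epi_mask
  px <- ph$image$pixels[bg]
  expect_gt(length(px), 1e5)
  cK <- sqrt(2) * gamma(8.5) / gamma(8)
  sigma_channel <- 2.05 / sqrt(16 - cK^2)
  expect_equal(mean(px), sigma_channel * cK, tolerance = 0.01)
  expect_equal(sd(px), 2.05, tolerance = 0.01)
  # moment-corrected estimator recovers the generating per-channel sigma
  expect_equal(estimate_sigma(px, "moment_corrected", coils = 8), sigma_channel,
               tolerance = 0.02)
})

test_that("noise-only myocardium concords with the matching noise model", {
  ph <- recovery_phantom(0, 0, seed = 88) # ~5900 myocardial pixels
  myo <- ph$image$pixels[myocardium_mask(ph$seg)]
  expect_gt(length(myo), 5000)
  cK <- sqrt(2) * gamma(8.5) / gamma(8)
  matching <- noise_model(2.05 / sqrt(16 - cK^2), 8)
  h <- intensity_histogram(round(myo))
  expect_gt(concordance(h, rayleigh_reference_curve(matching)), 95)
})

test_that("lesion geometry is validated and zero-amplitude lesions leave no truth", {
  base <- phantom_spec(image_shape = c(64L, 64L), pixel_spacing_mm = 1,
                       endo_radius_mm = 10, epi_radius_mm = 16,
                       background_side_mm = 8, seed = 5)
  zero <- phantom_spec(image_shape = c(64L, 64L), pixel_spacing_mm = 1,
                       endo_radius_mm = 10, epi_radius_mm = 16,
                       background_side_mm = 8,
                       lesions = list(lesion_wedge(0, pi, 0)), seed = 5)
  ph <- simulate_image(zero)
  expect_false(any(ph$truth))
  expect_identical(ph$image$pixels, simulate_image(base)$image$pixels)
  # a disc poking outside the annulus is rejected
  bad <- phantom_spec(image_shape = c(64L, 64L), pixel_spacing_mm = 1,
                      endo_radius_mm = 10, epi_radius_mm = 16,
                      background_side_mm = 8,
                      lesions = list(lesion_disc(c(0, 13), 6, 10)), seed = 5)
  expect_error(simulate_image(bad), class = "lgequant_spec_error")
  expect_error(phantom_spec(endo_radius_mm = 20, epi_radius_mm = 15),
               class = "lgequant_spec_error")
})

test_that("subject concordance decreases as the enhanced fraction grows", {
  conc <- vapply(c(0, 0.1, 0.2, 0.3, 0.4), function(f) {
    ph <- recovery_phantom(f, 10, seed = 99)
    quantify_all(to_8bit(ph$image), ph$seg)$concordance
  }, numeric(1))
  expect_true(all(diff(conc) < 0))
})

test_that("cohorts are reproducible and validated", {
  expect_error(simulate_cohort(0, 5, seed = 1), class = "lgequant_spec_error")
  expect_error(simulate_cohort(2, 2, enhancement_range = c(0.5, 1.5), seed = 1),
               class = "lgequant_spec_error")
  a <- simulate_cohort(3, 2, seed = 7, image_shape = c(96L, 96L),
                       pixel_spacing_mm = 1, endo_radius_mm = 12,
                       epi_radius_mm = 20)
  b <- simulate_cohort(3, 2, seed = 7, image_shape = c(96L, 96L),
                       pixel_spacing_mm = 1, endo_radius_mm = 12,
                       epi_radius_mm = 20)
  expect_identical(dplyr::select(a, -image, -seg, -truth),
                   dplyr::select(b, -image, -seg, -truth))
  expect_identical(a$image[[1]]$pixels, b$image[[1]]$pixels)
  expect_identical(a$group, rep(c("positive", "negative"), c(3, 2)))
  expect_true(all(a$true_fraction[1:3] > 0.15))
  expect_true(all(a$true_fraction[4:5] == 0))
})

test_that("the full pipeline recovers per-subject extent for a small cohort", {
  coh <- simulate_cohort(3, 1, contrast_range = c(8, 12), seed = 17,
                         image_shape = c(256L, 256L), pixel_spacing_mm = 1,
                         endo_radius_mm = 25, epi_radius_mm = 50)
  res <- quantify_cohort(coh)
  rc <- dplyr::filter(res, method == "RC")
  err <- rc$extent_percent - 100 * rc$true_fraction
  expect_true(all(abs(err) < 2))
})
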