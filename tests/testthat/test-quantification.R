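test_that("nSD thresholds are mean + n*SD of the normal-myocardium ROI", {
  roi <- c(3, 5, 7) # mean 5, sd 2
  expect_identical(sd_threshold(roi, 2), 9)
  expect_identical(sd_threshold(roi, 6), 17)
  set.seed(5)
  r <- runif(50, 0, 20)
  expect_lt(sd_threshold(r, 2), sd_threshold(r, 6))
  expect_error(sd_threshold(5, 2), class = "lgequant_roi_error")
})

test_that("enhancement classification is a strict threshold inside the myocardium", {
  px <- matrix(0, 10, 10)
  px[1, 1:7] <- 200
  img <- gray_image(px, 1, "8bit")
  myo <- matrix(TRUE, 10, 10)
  expect_identical(sum(classify_enhanced(img, myo, 255)), 0L)
  expect_identical(classify_enhanced(img, myo, -1), myo)
  expect_identical(sum(classify_enhanced(img, myo, 100)), 7L)
  # boundary: intensity equal to the threshold is NOT enhanced
  expect_identical(sum(classify_enhanced(img, myo, 200)), 0L)
})

test_that("extent is the pixel-count percentage and is antitone in the threshold", {
  myo <- matrix(TRUE, 10, 10)
  enh <- matrix(FALSE, 10, 10); enh[1, 1:7] <- TRUE
  expect_identical(extent_percent(enh, myo), 7.0)
  expect_identical(extent_percent(matrix(FALSE, 10, 10), myo), 0.0)
  expect_identical(extent_percent(myo, myo), 100.0)
  expect_error(extent_percent(enh, matrix(FALSE, 10, 10)),
               class = "lgequant_mask_error")
  expect_error(extent_percent(myo, enh), class = "lgequant_mask_error")
  # exhaustive check against a brute-force pixel scan on small random images
  set.seed(6)
  px <- matrix(sample(0:255, 64, replace = TRUE), 8)
  img <- gray_image(px, 1, "8bit")
  mask <- matrix(sample(c(TRUE, FALSE), 64, TRUE, prob = c(0.7, 0.3)), 8)
  extents <- vapply(0:255, function(t) {
    brute <- 0
    for (i in 1:8) for (j in 1:8)
      if (mask[i, j] && px[i, j] > t) brute <- brute + 1
    e <- extent_percent(classify_enhanced(img, mask, t), mask)
    expect_identical(e, 100 * brute / sum(mask))
    e
  }, numeric(1))
  expect_true(all(diff(extents) <= 0))
})

test_that("parametric maps partition the image into the three tissue labels", {
  myo <- disc_mask(16, 6) & !disc_mask(16, 3)
  enh <- myo & disc_mask(16, 6, center = 5)
  map <- parametric_map(myo, enh)
  expect_identical(sum(map == 2L), sum(enh))
  expect_identical(sum(map == 1L), sum(myo) - sum(enh))
  expect_identical(sum(map %in% 0:2), length(map))
  map0 <- parametric_map(myo, matrix(FALSE, 16, 16))
  expect_identical(sort(unique(as.vector(map0))), c(0L, 1L))
})

test_that("noise-only subjects: SD2 overestimates while SD6 and RC stay near zero", {
  ph <- recovery_phantom(0, 0, seed = 31)
  q <- quantify_all(to_8bit(ph$image), ph$seg)
  res <- tidy(q)
  ext <- setNames(res$extent_percent, res$method)
  expect_gt(ext["SD2"], ext["SD6"])
  expect_gt(ext["SD2"], ext["RC"])
  expect_lt(ext["RC"], 0.5)
  # SD2 flags roughly the upper-tail share implied by its 2-SD construction
  expect_gt(ext["SD2"], 0.5)
})

test_that("RC false-positive extent over noise-only subjects is bounded by the tail mass", {
  enhanced <- 0; myo_n <- 0
  for (seed in 41:45) {
    ph <- recovery_phantom(0, 0, seed = seed)
    q <- quantify_all(to_8bit(ph$image), ph$seg)
    rc <- dplyr::filter(q$results, method == "RC")
    enhanced <- enhanced + rc$n_enhanced
    myo_n <- myo_n + q$myo_pixel_count
  }
  expect_lte(100 * enhanced / myo_n, 100 * 1e-4 * (1 + 5 / sqrt(myo_n)))
})

test_that("RC recovers the true lesion extent within 2 points at contrast >= 8 sigma", {
  for (case in list(list(f = 0.20, c = 8, seed = 51),
                    list(f = 0.30, c = 10, seed = 52),
                    list(f = 0.40, c = 12, seed = 53))) {
    ph <- recovery_phantom(case$f, case$c, seed = case$seed)
    truth <- 100 * sum(ph$truth) / sum(myocardium_mask(ph$seg))
    q <- quantify_all(to_8bit(ph$image), ph$seg)
    rc_ext <- tidy(q)$extent_percent[tidy(q)$method == "RC"]
    expect_lt(abs(rc_ext - truth), 2)
  }
})

test_that("quantify_all propagates thresholds monotonically and reports bands", {
  ph <- recovery_phantom(0.25, 10, seed = 61)
  img8 <- to_8bit(ph$image)
  q <- quantify_all(img8, ph$seg, two_band = TRUE)
  # lower threshold never yields smaller extent
  res <- dplyr::arrange(tidy(q), threshold)
  expect_true(all(diff(res$extent_percent) <= 0))
  # two-band extension splits the RC detection at the SD6 threshold
  rc_ext <- tidy(q)$extent_percent[tidy(q)$method == "RC"]
  sd6 <- tidy(q)$threshold[tidy(q)$method == "SD6"]
  rc <- tidy(q)$threshold[tidy(q)$method == "RC"]
  if (rc < sd6)
    expect_equal(sum(q$bands$extent_percent), rc_ext, tolerance = 1e-9)
  expect_identical(q$bands$band, c("mild", "higher"))
  # glance/tidy surfaces
  expect_named(glance(q), c("concordance", "sigma", "coils", "myo_pixel_count"))
  expect_s3_class(autoplot(q), "ggplot")
})
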