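test_that("pdf matches the closed-form chi density, normalizes, and respects the unit step", {
  for (K in c(1L, 2L, 4L, 8L)) {
    for (s in c(0.5, 2.05, 10)) {
      m <- noise_model(s, K)
      expect_equal(integrate(function(x) rayleigh_pdf(x, m), 0, 40 * s,
                             rel.tol = 1e-10)$value,
                   1, tolerance = 1e-6)
      grid <- seq(1e-3 * s, 12 * s, length.out = 20001)
      expect_equal(grid[which.max(rayleigh_pdf(grid, m))],
                   s * sqrt(2 * K - 1),
                   tolerance = 2 * (grid[2] - grid[1]) / (s * sqrt(2 * K - 1)))
      # log-space implementation agrees with the naive factorial formula
      expect_equal(rayleigh_pdf(grid[1:500], m), oracle_pdf(grid[1:500], s, K),
                   tolerance = 1e-12)
    }
  }
  m <- noise_model(2.05, 8)
  expect_identical(rayleigh_pdf(-1, m), 0)
  expect_identical(rayleigh_pdf(0, m), 0)
  # K = 1 reduces to the classical Rayleigh density
  m1 <- noise_model(1.7, 1)
  x <- seq(0.01, 10, by = 0.01)
  expect_equal(rayleigh_pdf(x, m1), (x / 1.7^2) * exp(-x^2 / (2 * 1.7^2)),
               tolerance = 1e-12)
  expect_error(noise_model(-1, 8), class = "lgequant_parameter_error")
  expect_error(noise_model(2, 0), class = "lgequant_parameter_error")
})

test_that("cdf agrees with quadrature of the pdf and has median 0.5", {
  m <- noise_model(2.05, 8)
  expect_identical(rayleigh_cdf(0, m), 0)
  expect_identical(rayleigh_cdf(-3, m), 0)
  mode <- 2.05 * sqrt(15)
  expect_equal(rayleigh_cdf(mode, m), oracle_cdf(mode, 2.05, 8), tolerance = 1e-9)
  # median found by bisection on the package cdf is the 0.5 quantile
  lo <- 0; hi <- 100
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (rayleigh_cdf(mid, m) < 0.5) lo <- mid else hi <- mid
  }
  expect_equal(rayleigh_cdf((lo + hi) / 2, m), 0.5, tolerance = 1e-9)
  expect_equal((lo + hi) / 2, rayleigh_quantile(0.5, m), tolerance = 1e-8)
  grid <- seq(0, 30, by = 0.1)
  expect_true(all(diff(rayleigh_cdf(grid, m)) >= 0))
})

test_that("rc_threshold matches an independent bisection oracle and is monotone", {
  m <- noise_model(2.05, 8)
  t_pkg <- rc_threshold(m)
  t_oracle <- ceiling(oracle_quantile(1 - 1e-4, 2.05, 8))
  expect_identical(t_pkg, t_oracle)
  expect_identical(t_pkg, 14)
  # noisier background shifts the cutoff to a higher value
  expect_gt(rc_threshold(noise_model(4.10, 8)), rc_threshold(noise_model(2.05, 8)))
  sigmas <- c(0.5, 1, 2.05, 4.1, 8)
  thr <- vapply(sigmas, function(s) rc_threshold(noise_model(s, 8), integer = FALSE),
                numeric(1))
  expect_true(all(diff(thr) > 0))
  # smaller tail mass -> higher threshold; degenerate noise -> threshold at floor
  expect_gt(rc_threshold(m, 1e-6, integer = FALSE),
            rc_threshold(m, 1e-2, integer = FALSE))
  expect_lte(rc_threshold(noise_model(1e-8, 8)), 1)
  expect_error(rc_threshold(noise_model(50, 8)), class = "lgequant_saturation_error")
  expect_error(rc_threshold(m, tail_mass = 0.7), class = "lgequant_parameter_error")
})

test_that("sigma estimation recovers the generating noise level", {
  expect_error(estimate_sigma(c(3, 3, 3, 3)),
               class = "lgequant_degenerate_background_error")
  expect_error(estimate_sigma(2), class = "lgequant_roi_error")
  set.seed(101)
  px <- simulate_magnitude(1e5, sigma = 2.0, coils = 8)
  expect_equal(estimate_sigma(px, "moment_corrected", coils = 8), 2.0,
               tolerance = 0.02)
  # direct estimate is the chi-magnitude SD: off by the closed-form factor
  direct <- estimate_sigma(px, "direct")
  cK <- sqrt(2) * gamma(8.5) / gamma(8)
  expect_equal(direct / 2.0, sqrt(16 - cK^2), tolerance = 0.02)
  # window offset of unwindowed model samples is ~0
  expect_equal(window_offset(px, noise_model(2.0, 8)), 0, tolerance = 0.05)
})

test_that("Gaussian fit recovers exact Gaussian histograms and flags thin data", {
  x <- 0:255
  exact <- 8 * exp(-(x - 40)^2 / (2 * 5^2))
  h <- lgequant:::new_intensity_histogram(exact, n_pixels = 1000L)
  fit <- fit_gaussian_to_histogram(h)
  expect_lt(fit$fitting_error_percent, 0.5)
  expect_equal(fit$mean, 40, tolerance = 1e-3)
  expect_equal(fit$sd, 5, tolerance = 1e-3)
  thin <- lgequant:::new_intensity_histogram(c(50, 50, rep(0, 254)), n_pixels = 4L)
  expect_error(fit_gaussian_to_histogram(thin),
               class = "lgequant_insufficient_data_error")
})

test_that("Gaussian fit of chi-sampled histograms lands near the chi mean with nonzero error", {
  set.seed(7)
  px <- round(simulate_magnitude(1e5, sigma = 2.05, coils = 8))
  h <- intensity_histogram(px)
  fit <- fit_gaussian_to_histogram(h)
  expect_gt(fit$fitting_error_percent, 0)
  chi_mean <- 2.05 * sqrt(2) * gamma(8.5) / gamma(8)
  expect_equal(fit$mean, chi_mean, tolerance = 0.05)
})

test_that("measured-vs-Gaussian paired t is zero at identity, antisymmetric, and guards degeneracy", {
  set.seed(7)
  h <- intensity_histogram(round(simulate_magnitude(2e4, 2.05, 8)))
  fit <- fit_gaussian_to_histogram(h)
  t1 <- gaussian_vs_measured_test(h, fit)
  expect_true(is.finite(t1$statistic))
  # identical curves -> t = 0, p = 1
  self_fit <- fit
  self_fit$fitted <- h$percent
  expect_equal(gaussian_vs_measured_test(h, self_fit)$statistic, 0)
  # swapping measured and fitted negates the statistic
  swapped_hist <- lgequant:::new_intensity_histogram(fit$fitted, n_pixels = 1L)
  swapped_fit <- fit
  swapped_fit$fitted <- h$percent
  t2 <- gaussian_vs_measured_test(swapped_hist, swapped_fit)
  expect_equal(t2$statistic, -t1$statistic, tolerance = 1e-12)
  # constant nonzero offset has zero difference variance
  off_fit <- fit
  off_fit$fitted <- h$percent + 0.25
  expect_error(gaussian_vs_measured_test(h, off_fit),
               class = "lgequant_degenerate_difference_error")
})
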