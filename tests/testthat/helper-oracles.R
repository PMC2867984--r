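# Independent oracles, kept deliberately naive and separate from the package
# implementation paths they check.

# Chi (2K df, scale sigma) density written directly from the closed form,
# with explicit factorial -- usable for the K values exercised in tests.
oracle_pdf <- function(m, sigma, K) {
  ifelse(m > 0,
         m^(2 * K - 1) / (2^(K - 1) * sigma^(2 * K) * factorial(K - 1)) *
           exp(-m^2 / (2 * sigma^2)),
         0)
}

# CDF by adaptive quadrature of the naive density.
oracle_cdf <- function(m, sigma, K) {
  vapply(m, function(mi) {
    if (mi <= 0) return(0)
    stats::integrate(oracle_pdf, 0, mi, sigma = sigma, K = K,
                     rel.tol = 1e-12, abs.tol = 1e-14)$value
  }, numeric(1))
}

# Quantile by bisection on the quadrature CDF.
oracle_quantile <- function(p, sigma, K, lo = 0, hi = 100 * sigma) {
  while (hi - lo > 1e-10 * sigma) {
    mid <- (lo + hi) / 2
    if (oracle_cdf(mid, sigma, K) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Mann-Whitney AUC by exhaustive pair counting, ties credited 1/2.
# Positives are the low-score (diseased) group.
oracle_auc <- function(pos, neg) {
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p < n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Best Youden cutoff by exhaustive evaluation of every candidate cutoff
# (positive called when score < cutoff), ties toward higher specificity.
oracle_best_cutoff <- function(pos, neg) {
  cand <- sort(unique(c(pos, neg)))
  best <- NULL
  for (c in cand) {
    sens <- mean(pos < c)
    spec <- mean(neg >= c)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec))
      best <- list(cutoff = c, sens = sens, spec = spec, j = j)
  }
  best
}

# Shared small phantoms for the pipeline tests: ~5900 myocardial pixels on a
# 1 mm grid so per-subject extent recovery is testable at the 2-point level.
recovery_phantom <- function(fraction, contrast, seed) {
  lesions <- if (fraction > 0)
    list(lesion_wedge(pi / 3, fraction * 2 * pi, contrast)) else list()
  simulate_image(phantom_spec(
    image_shape = c(256L, 256L), pixel_spacing_mm = 1,
    endo_radius_mm = 25, epi_radius_mm = 50,
    lesions = lesions, seed = seed))
}

disc_mask <- function(n, r, center = (n + 1) / 2) {
  d <- sqrt(outer((1:n - center)^2, (1:n - center)^2, "+"))
  d < r
}
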