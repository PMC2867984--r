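---
title: "Noise-model-based quantification of late gadolinium enhancement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-model-based quantification of late gadolinium enhancement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgequant)
```

## The problem

Late gadolinium enhancement (LGE) imaging detects myocardial fibrosis: ten
minutes after contrast injection, scar retains gadolinium and appears bright
in a T1-weighted inversion-recovery image whose inversion time has been tuned
to null normal myocardium. Quantifying *how much* myocardium is enhanced
requires a threshold, and the common practice — a normal-myocardium ROI mean
plus n standard deviations (n = 2, 5, 6, ...) — is sensitive to where the
operator puts the ROI and to the image noise level. This package implements
a threshold derived from the physics of the noise itself, plus a
histogram-concordance statistic that summarizes how "noise-like" a
myocardial wall is, for whole-subject classification.

## Signal model

With K phased-array coils combined by root-sum-of-squares, a pixel with true
signal amplitude A has magnitude
$m = \sqrt{\sum_{k=1}^{K} (A_k + n_{k,r})^2 + n_{k,i}^2}$ with i.i.d.
Gaussian channel noise of standard deviation $\sigma$. For $A = 0$ — image
background, or perfectly nulled myocardium — $m/\sigma$ is chi-distributed
with $2K$ degrees of freedom:

$$p(m) = \frac{m^{2K-1}}{2^{K-1}\sigma^{2K}(K-1)!}
         \exp\!\Big(\!-\frac{m^2}{2\sigma^2}\Big)\,\varepsilon(m),$$

the generalized Rayleigh distribution (`rayleigh_pdf()`, evaluated in log
space so large K and m cannot overflow the factorial and power terms). Its
mode is $\sigma\sqrt{2K-1}$, its mean $c_K\sigma$ with
$c_K=\sqrt2\,\Gamma(K+\tfrac12)/\Gamma(K)$, and its SD
$\sigma\sqrt{2K-c_K^2}$. For K = 8 (the standard cardiac array) the shape is
close to Gaussian; `fit_gaussian_to_histogram()` quantifies how close with a
Levenberg–Marquardt fit and a scale-invariant L1 fitting error, and
`gaussian_vs_measured_test()` compares the curves by a bin-paired t test.
The paired units of that test are histogram bins on the joint support; this
is one of several defensible constructions and we do not claim it is the
only one.

## Two σ conventions

The background ROI measures the SD of the *magnitude*, which is
$\sigma\sqrt{2K - c_K^2} \approx 0.70\,\sigma$ at K = 8 — not the
per-channel σ the chi formula expects. `estimate_sigma()` therefore offers:

* `direct` — the sample SD verbatim, the convention of plugging the
  background SD straight into the Rayleigh curve;
* `moment_corrected` — the sample SD divided by $\sqrt{2K - c_K^2}$, which
  recovers the generating σ on simulated noise (tested to within 2 % at
  10⁵ pixels).

`quantify_all()` defaults to `moment_corrected`. With `direct`, the rendered
curve is ~30 % too narrow and its upper end falls *below* the bulk of the
nulled-myocardium distribution, which would flag a large fraction of normal
myocardium as enhanced — inconsistent with the near-zero false-positive
behaviour the RC method is designed for.

## Windowing and the location offset

The pipeline converts raw images to a fixed 0–255 grayscale by min-to-max
windowing (`to_8bit()`): an affine map, so any linear acquisition windowing
is nulled, and the maximum is always 255, the minimum always 0. Subtracting
the image minimum has a consequence that is easy to miss: the minimum of a
chi-distributed noise field over ~10⁵ pixels is about $1.4\,\sigma$ above
zero, so the 8-bit noise distribution is a chi *shifted left* by a few
intensity units. `quantify_all(align_background = TRUE)` (the default)
estimates this shift from the background ROI as
`offset = mean(background) − c_K σ̂` — the model pins the noise mean at
$c_K\sigma$ — and translates the reference curve and the RC threshold by it.
Without the alignment the reference curve sits a few bins right of the
measured histogram and both the concordance and the extent recovery degrade.
(Under the `direct` convention the estimated offset happens to be close to
zero: the narrower curve's mean $c_K \cdot 0.70\,\sigma$ lands near the
shifted data by near-cancellation of the two effects — location is absorbed,
width is not.)

## The three methods

All methods operate on the 8-bit slice restricted to the myocardium (the set
difference of the filled epicardial and endocardial contours), with strict
inequality at the threshold:

* **SD2 / SD6** (`sd_threshold()`): normal-myocardium ROI mean + 2 or 6
  sample SDs. By construction SD2 flags ~2 % of genuinely normal myocardium.
* **RC** (`rc_threshold()`): the smallest intensity with
  $F(t) \ge 1 - \text{tail\_mass}$, rounded up to the next integer bin,
  default `tail_mass = 1e-4`. An unbounded density has no literal "maximal
  intensity"; the 1 − 10⁻⁴ quantile is where a rendered curve visually ends
  at histogram precision, and it keeps the cutoff strictly increasing in σ,
  so noisier images are thresholded higher rather than over-segmented. A
  threshold beyond 255 raises a saturation error.

Extent is the enhanced-pixel count as a percentage of myocardial pixels;
with uniform slice thickness and no gap this equals the mass fraction.
Multi-slice extents should be pooled at the pixel level (the per-subject
tables returned by `quantify_cohort()` do this implicitly for single-slice
subjects); a mean-of-slices aggregation would weight thin-walled slices up.
An optional two-band split of the RC detection (RC-to-SD6 = "mild", above
SD6 = "higher") is provided as a labelled extension, not a standard method.

## Concordance and classification

`rayleigh_reference_curve()` renders the model on the 0–255 integer grid by
per-bin integration of the CDF (sampling the density at bin centres would
bias narrow curves). `concordance()` is the bin-wise intersection

$$C = 100\,\frac{\sum_i \min(m_i, r_i)}{\sum_i r_i},$$

computed on the same integer grid as the 8-bit pipeline so it is exactly
reproducible; the denominator is the reference area as defined even though
it is ≈ 100 by construction. A degenerate reference (zero area) is an error.

`concordance_roc()` sweeps a cutoff over all observed concordance values,
calling a subject diseased when its concordance is strictly below the
cutoff. The trapezoidal AUC equals the Mann–Whitney pairwise probability
with ties counted ½ (verified against exhaustive pair counting). The
reported operating point maximizes Youden's J; the criterion is a package
choice — ties are broken toward higher specificity, matching the screening
use of the statistic.

## The phantom simulator

`simulate_image()` draws every pixel as the root-sum-of-squares of K complex
channels, so background and nulled myocardium follow the chi model *exactly*
and lesions follow its noncentral analogue — no Gaussian shortcut. Design
choices:

* `phantom_spec(sigma = )` is the target **background magnitude SD** (the
  quantity a background ROI reports); the per-channel noise is derived from
  it. This keeps "the SD measured in the background ROI" the ground truth.
* Lesion and residual-myocardium amplitudes are in multiples of the
  per-channel σ, the natural contrast unit of the model.
* A bright blood pool (250 raw units by default) pins the window scale, so
  the 8-bit background SD lands near the configured value — with the default
  2.05 at K = 8, the regime of a typical 1.5 T cardiac acquisition.
* Wedge lesions make the enhanced fraction exactly controllable; lesion
  edges are hard (no partial-volume blur), which favours threshold methods.
* The background ROI box is placed in a lesion-free corner and checked to be
  disjoint from the anatomy; the normal-myocardium ROI is the lesion-free
  part of the annulus.

Default cohort conditions (`simulate_cohort()`): 40 diseased / 20 normal
subjects, enhanced fractions uniform on 20–40 %, contrasts uniform on
8–12 σ, 256×256 pixels at 1.5625 mm (400 mm field of view, 256 matrix),
K = 8, σ = 2.05. Per-subject seeds derive from one master seed, so a cohort
is bit-reproducible.

What the simulator does **not** emulate: realistic cardiac anatomy and
motion, coil-sensitivity inhomogeneity, partial-volume edges, spatially
correlated (parallel-imaging) noise, patchy multi-focal fibrosis, or
operator variability in contouring. Passing tests therefore demonstrate
internal consistency of the method under its own noise model, not clinical
accuracy on patient images.

## Numerical choices and degenerate inputs

* 8-bit rounding is half-up; a constant image maps to all zeros with a
  warning.
* Gaussian-fit initialization: histogram moments; `nlsLM` with 200-iteration
  cap and 1e-8 relative tolerance; non-convergence raises a fit-failure
  condition. Fewer than 3 nonzero bins is an error.
* Zero-variance bin differences in the paired t test: identically zero
  differences give t = 0; a nonzero constant difference raises a degenerate
  condition instead of an infinite statistic.
* A constant background ROI (SD = 0) is a degenerate-background error; a
  zero-denominator CNR is a degenerate-ROI error.
* `rc_threshold(sigma → 0)` tends to the bottom bin (the integer rounding
  floors at the next bin above an infinitesimal quantile).
* AUC tie handling is ½ credit throughout.

## Problem sizes

The test suite runs phantoms of 64–512 pixels square: ~780 myocardial pixels
for cohort subjects (a realistic single-slice wall), ~5 900 for per-subject
extent-recovery checks, and ≥ 10⁴ pixels per region for the
nulled-myocardium/background mean-ratio check, with 10⁵-sample draws for the
estimator-bias checks. These sizes put simulation error comfortably below
the tolerances being asserted while keeping the default suite under a
minute of simulation time.

## Known limitations

* The concordance of real control subjects reflects imperfect nulling,
  motion and contouring error; simulated controls sit a few points higher.
* The RC method assumes the background ROI noise is representative of the
  myocardial noise; surface-coil shading violates this and is not corrected.
* Only hard-thresholding methods are implemented; FWHM-style core/border
  analyses and connected-component filtering are out of scope.
* DICOM files are not read directly; export pixel arrays to CSV/TSV with a
  spacing sidecar.
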