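# lgequant

Quantification of late gadolinium enhancement (LGE) in cardiac magnetic
resonance, built around an adaptive noise-derived threshold (the
Rayleigh-curve, or **RC**, method) and the two fixed cutoffs it is usually
compared against (**SD2** and **SD6**). The package is aimed at cardiac-MR
researchers who want a reproducible, scriptable alternative to manual
windowing-and-eyeballing when measuring fibrosis burden in hypertrophic
cardiomyopathy (HCM) and similar diseases.

## The model

In an inversion-recovery LGE acquisition the inversion time is chosen to null
normal myocardium, so a healthy myocardial wall contains *only noise*. For a
magnitude image combined from K phased-array coils by root-sum-of-squares,
noise-only pixels follow a generalized Rayleigh distribution — a chi
distribution with 2K degrees of freedom scaled by the per-channel noise
level σ:

    p(m) = m^(2K−1) / (2^(K−1) σ^(2K) (K−1)!) · exp(−m² / 2σ²),  m ≥ 0

with mode σ√(2K−1), mean c_K σ where c_K = √2 Γ(K+½)/Γ(K), and variance
σ²(2K − c_K²). For K = 1 this is the classical Rayleigh distribution.

From this, on the fixed 0–255 grayscale obtained by min-to-max windowing:

* **RC threshold** — σ is estimated from a background ROI (pure noise), the
  ideal noise curve is rendered, and any myocardial pixel brighter than the
  top of that curve (the 1 − 10⁻⁴ quantile, rounded up to the next intensity
  bin) is called enhanced. Noisier images automatically get a higher cutoff.
* **Concordance** — the measured myocardial intensity histogram is overlaid
  on the ideal noise curve; the intersection area as a percentage of the area
  under the noise curve is near 100 % for normal myocardium and drops when
  enhancement moves pixels rightward. A subject-level ROC analysis of this
  statistic separates diseased from normal hearts.
* **SD2 / SD6** — thresholds at the mean of a visually normal myocardial ROI
  plus 2 or 6 standard deviations, for comparison.

A K-coil phantom simulator (annulus + blood pool + wedge/disc lesions with
exact ground truth) makes the entire pipeline testable without patient data.

## Worked example

Simulate one HCM-like slice (lesion covering 30 % of the myocardium at 10σ
contrast), quantify it with all three methods, and inspect the result:

```r
library(lgequant)

ph <- simulate_image(phantom_spec(
  lesions = list(lesion_wedge(0.5, 0.3 * 2 * pi, 10)), seed = 7))
q <- quantify_all(to_8bit(ph$image), ph$seg)
q
#> <lge_quant> 780 myocardial pixels, concordance 70.0%
#> # A tibble: 3 × 4
#>   method threshold n_enhanced extent_percent
#>   <chr>      <dbl>      <int>          <dbl>
#> 1 SD2         11.1        243           31.2
#> 2 SD6         19.4        234           30
#> 3 RC          17          234           30
```

The true enhanced fraction is 30 %: the RC threshold (17, derived from the
background noise alone) recovers it exactly, SD6 matches here too, and SD2
overestimates. The concordance of 70 % reflects the large enhanced mass; a
noise-only control simulated the same way scores ≈ 94 %. `tidy(q)` /
`glance(q)` return the tables above, `autoplot(q)` draws the parametric map
(pink = enhanced), and `plot_histogram_overlap(q$histogram, q$reference)`
shows the curve intersection behind the concordance number.

Cohort-level, the concordance statistic separates groups:

```r
coh  <- simulate_cohort(10, 5, seed = 42)       # 10 HCM-like, 5 normal
res  <- quantify_cohort(coh)
subj <- dplyr::distinct(res, subject_id, group, concordance)
concordance_roc(subj)
#> <concordance_roc> 10 positive / 5 negative subjects
#>   AUC 1.000; cutoff 93.8% -> sensitivity 100.0%, specificity 100.0%
```

A thin command-line surface wraps the same functions
(`inst/cli/lgequant.R`; subcommands `simulate`, `quantify`, `concordance`,
`roc`, composable through CSV/YAML/PNG files).

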