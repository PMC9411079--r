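---
title: "Centroiding profile mass spectra with data quality scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centroiding profile mass spectra with data quality scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dqcentroid)
```

## The problem

High-resolution mass spectrometers record *profile* spectra: each mass peak
is sampled as a handful of (m/z, intensity) points that trace a peak shape.
Most downstream software expects *centroid* spectra, where every peak is
reduced to a single (m/z, intensity) pair. Conventional centroiding throws
away the peak width, the peak area, and — crucially — any notion of how
trustworthy the reduction was. Peaks overlapping with isobaric neighbours or
unresolved isotopic fine structure yield centroids that look exactly like
clean monoisotopic ones.

`dqcentroid` converts profile spectra (mzML/mzXML) to a centroid table that
keeps this information. Every centroid carries the fitted Gaussian width
(sigma and FWHM), the Gaussian peak area, and a **Data Quality Score (DQS)**
in [0, 1] that quantifies the agreement of the underlying profile with a
Gaussian peak model through error propagation.

## The model

Orbitrap peak profiles are well described by a Gaussian,

$$ I(x) = I_0 \exp\!\left( -\frac{(x - x_0)^2}{2\sigma^2} \right), $$

whose logarithm is a second-order polynomial
$\ln I(x) = \beta_0 + \beta_1 x + \beta_2 x^2$ with

$$ x_0 = -\frac{\beta_1}{2\beta_2}, \qquad
   \sigma = \sqrt{-\frac{1}{2\beta_2}}, \qquad
   \ln I_0 = \beta_0 - \frac{\beta_1^2}{4\beta_2}, \qquad
   A = I_0\,\sigma\sqrt{2\pi}. $$

This linearization turns millions of iterative non-linear fits into cheap
weighted linear regressions while still delivering coefficient uncertainties.
Because the log transform inflates noise in the peak tails, points are
weighted by their intensity share, $w_i = (I_i/\sum I)^p$ with $p = 2$ by
default (`weight_power`); the weights are scale-invariant, so rescaling a
profile's intensities never changes the fitted position or width.

The coefficient covariance is the standard weighted-least-squares estimate
$\mathrm{MSE}\,(X^\top W X)^{-1}$ with
$\mathrm{MSE} = \frac{1}{n-3}\sum w_i (y_i - \hat y_i)^2$ on $n - 3$ degrees
of freedom. Propagating it through the parameter map gives standard errors
for height and width, and the **relative area error**
$\Delta A / A = \sqrt{(\Delta I_0/I_0)^2 + (\Delta\sigma/\sigma)^2}$ —
no cross term between height and width is included; each term however uses
the full coefficient covariance internally. The score is

$$ \mathrm{DQS} = 1 - \operatorname{erf}\!\left(\frac{\Delta A}{A}\right), $$

so a perfectly determined area scores 1 and an unbounded error scores 0.
Categories I–IV cut the score at the DQS values of 1%, 5% and 33% relative
area error (computed at run time from the error function, with the boundary
assigned to the better category).

## Pipeline stages and their rules

1. **Isolation** (`isolate_profiles`). Resolved Orbitrap profiles are
   surrounded by true zero intensities, which act as predefined boundaries;
   only exact zeros count, no epsilon. Overlapping profiles inside one
   nonzero run are split at *valley points* — strict local minima — and the
   valley point is assigned to **both** neighbours. A flat plateau of equal
   minimal values between higher neighbours is treated as one valley at its
   leftmost point, which keeps splitting deterministic. Because some
   converters omit rather than store zeros, an m/z step larger than
   `gap_factor` (default 4) times the run's median step also acts as a
   boundary; the default is inert on fully zero-padded data.
2. **Regression** (`fit_profiles`). Profiles need at least 4 points (a
   residual degree of freedom); shorter ones are rejected with reason
   `min_points`. Fits can be solved per profile (3×3 normal equations) or
   as one block-diagonal sparse Vandermonde system per batch (`Matrix`);
   both paths agree to well below 1e-9 and are covered by tests.
3. **Back-transformation** (`backtransform`). Fits with $\beta_2 \ge 0$ do
   not describe a downward-opening parabola (the width would be complex)
   and are rejected with reason `beta2_nonneg`. No further silent filters
   are applied; instead the flag `apex_inside` reports whether the fitted
   centroid lies inside the profile's m/z range so users can filter
   themselves.
4. **Scoring** (`score_peak`, `dqs_from_relative_error`, `categorize`).
5. **Output** (`write_centroid_table`). A fixed 13-column CSV, sorted by
   scan and centroid m/z, floats at 12 significant digits; a missing
   retention time stays an empty field rather than a fake 0. Rejected
   profiles are reported with coded reasons, never silently dropped, so
   `profiles found = centroids + rejects` always holds.

## Numerical conditioning

Raw m/z values near 200 with widths near 1e-3 make the Vandermonde normal
equations catastrophically ill-conditioned (column scales 1, 1e2, 1e5 —
squared in the normal matrix). Before solving, each profile's x-axis is
centered at its (leftmost) maximum-intensity point and scaled by its
half-width; coefficients and covariance are transformed back exactly
afterwards. This is a pure conditioning device — reported coefficients refer
to centered coordinates with the shift recorded, and recovery of noiseless
Gaussians is exact to ~1e-14 relative across m/z 100–1000.

## The synthetic generator

`generate_spectrum` emulates the data this pipeline targets, with known
ground truth:

* **Widths** follow the Orbitrap-like resolving-power law
  $R(m) = r_\mathrm{ref}\,(200/m)^{0.5}$ with $r_\mathrm{ref} = 70000$ at
  m/z 200 (a standard full-scan MS1 setting), via `orbitrap_width_model`.
* **Sampling**: each group of overlapping peaks is sampled on a uniform
  grid of step FWHM/`points_per_fwhm` over ±3σ, with a random grid phase.
  The default density 2.7 yields profiles of ~5–9 points (mean ≈ 6.9),
  the sparsity regime Orbitrap full scans actually produce. Intensities
  below 1 count are recorded as zero (detector floor) and every run is
  flanked by explicit zeros.
* **Noise** is multiplicative log-normal, $I\,e^{\varepsilon}$ with
  $\varepsilon \sim N(0, \mathrm{cv})$ — consistent with the log-domain
  regression assumptions. No instrument noise model was prescribed for this
  design; this is the generator's largest assumption and is isolated in one
  place. An additive component can be emulated by lowering
  `intensity_floor` and adding a baseline externally.
* **Randomness** uses R's default Mersenne-Twister via `set.seed`, so a
  fixed seed reproduces spectra bit-identically across platforms.
* Randomly placed peaks are respaced so their sampling windows never touch
  (`ensure_separated`); explicitly supplied peak lists are taken verbatim,
  which is how controlled overlap experiments are built.

What the generator does **not** emulate: Fourier-transform apodization
artifacts (real Orbitrap residuals are smoother than independent noise),
Lorentzian tails, isotopic patterns, baseline drift, and the chromatographic
domain. Passing the synthetic recovery tests therefore demonstrates
correctness of the algorithm, not instrument-level accuracy claims.

## Overlap behaviour

`overlap_experiment` generates pairs of equal-height peaks at controlled
center separations (in multiples of σ) and reports the DQS of everything
the pipeline produces. Down to ≈2σ separation the summed profile retains a
valley and is split into two (mutually contaminated) profiles whose DQS
degrades steadily as the peaks approach — at 6σ the score is limited only
by noise, around 3σ it bottoms out near 0.87 at 1% noise. Below the valley
threshold a single merged profile is fitted. Its score is lower than an
isolated peak's under the same noise, but **not** lower than the score at
intermediate separations: two Gaussians ~1.5σ apart sum to a curve that is
itself close to one wider Gaussian, and the merged profile carries twice
the points, so the score partially recovers. DQS flags contaminated
centroids well in the partially-resolved regime; a fully merged pair is
indistinguishable from a single clean peak by Gaussian agreement alone —
a known limitation inherent to any shape-agreement score.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `weight_power` | 2 | Exponent of the intensity-share weights; 0 = unweighted. |
| `min_points` | 4 | Minimum profile size; below it no residual degree of freedom exists. |
| `gap_factor` | 4 | Implicit-zero rule, in multiples of the run's median grid step. |
| `ppm_tol` | 3 | Cross-scan grouping tolerance (typical EIC mass window), ppm. |
| `max_gap` | 2 | Maximum consecutive missing scans inside a centroid group. |
| `min_size` | 10 | Minimum group size for m/z precision estimates. |
| `r_ref`, `exponent` | 70000, 0.5 | Width-model anchor and decay. |
| `points_per_fwhm` | 2.7 | Synthetic grid density (~6.9 points/profile). |
| `noise_cv` | 0 | Multiplicative noise coefficient of variation. |

## Worked example

```{r example}
tr <- generate_spectrum(n_peaks = 5, noise_cv = 0.01, seed = 42)
res <- centroid_spectrum(tr$spectrum)
res$centroids[, c("mz_centroid", "height", "sigma", "dqs", "category",
                  "n_points")]
```

Cross-scan m/z precision, the construction behind per-category precision
comparisons, uses `group_centroids`:

```{r groups}
spectra <- lapply(1:12, function(i)
  generate_spectrum(peaks = data.frame(x0 = 200, height = 1e6),
                    noise_cv = 0.01, seed = i, scan_id = paste0("scan=", i),
                    scan_index = i, retention_time = i)$spectrum)
cent <- centroid_spectra(spectra)$centroids
g <- group_centroids(cent)
g[[1]]
```

And the resolution–m/z relationship over a full mass range:

```{r powerlaw}
tr <- generate_spectrum(n_peaks = 50, noise_cv = 0, seed = 1)
cent <- centroid_spectrum(tr$spectrum)$centroids
fit_resolution_power_law(cent$mz_centroid,
                         mass_resolution(cent$mz_centroid, cent$fwhm))
```

## Validation strategy and problem sizes

The test suite validates every stage against independent oracles rather
than against itself: the parabola coefficients and covariance against R's
weighted `lm`; the recovered Gaussian parameters against an iterative
non-linear least-squares fit (`minpack.lm`), which is exact on noiseless
data and agrees within 0.1 σ̂ on 1000 noisy profiles; the error function
against numerical integration of its defining integral; the blocked sparse
solver against per-profile solves. Simulation sizes (batches of 100–200
peaks, 1000-profile recovery runs, 200-replicate overlap experiments) were
chosen so the entire suite completes in well under a minute on one core
while keeping Monte-Carlo margins wide relative to the asserted tolerances.

## Known limitations

* The Gaussian model only: Lorentzian or bi-Gaussian (TOF) peak shapes are
  out of scope, though strongly asymmetric profiles are still flagged by a
  low DQS.
* No deconvolution of overlapping profiles — deliberately: valley splitting
  plus scoring keeps the pipeline linear-time, and the DQS marks the
  affected centroids instead.
* Fully merged peak pairs score high (see *Overlap behaviour*).
* DQS reflects coefficient precision; with many points a mildly misfitting
  profile can still earn a decent score.
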